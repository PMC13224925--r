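# Synthetic structures with exactly known geometry.
#
# Ideal alpha-helix constants (1.5 A rise, 100 deg twist, 2.3 A C-alpha
# radius) are textbook values chosen so that secondary-structure windows,
# axis fits, separations and scores have closed-form expected values; the
# fixtures make every measurement in the package testable without any
# downloaded structure. They carry no physical realism beyond that (C-alpha
# traces, no sidechains except the atoms clash fixtures plant).

#' Ideal-helix parameters
#'
#' @param n_res Number of residues.
#' @param rise Rise per residue along the axis, angstrom (default 1.5).
#' @param twist Rotation per residue, degrees (default 100).
#' @param radius C-alpha distance from the axis, angstrom (default 2.3).
#' @param origin Position of the first C-alpha's axial foot point.
#' @param direction Unit axis direction (N to C).
#' @param phase Angular position of the first residue, degrees.
#' @return A list of class `helix_params`.
#' @export
helix_params <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                         origin = c(0, 0, 0), direction = c(0, 0, 1),
                         phase = 0) {
  stopifnot(n_res >= 1, rise > 0, radius >= 0)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) hf_config_error("helix direction must be non-zero")
  structure(list(n_res = as.integer(n_res), rise = rise, twist = twist,
                 radius = radius, origin = origin,
                 direction = direction / nrm, phase = phase),
            class = "helix_params")
}

# proper rotation taking +z onto `dir` (Rodrigues; antiparallel handled)
rotation_from_z <- function(dir) {
  z <- c(0, 0, 1)
  v <- c(z[2] * dir[3] - z[3] * dir[2],
         z[3] * dir[1] - z[1] * dir[3],
         z[1] * dir[2] - z[2] * dir[1])
  c_ <- sum(z * dir)
  if (sqrt(sum(v^2)) < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 deg about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' C-alpha coordinates of an ideal helix
#'
#' Generates `n_res` C-alpha positions on an ideal helical curve about the
#' stated axis; the first-to-last displacement points along `+direction`.
#'
#' @param p A [helix_params()] object.
#' @return Tibble with `resno` (1..n), `x`, `y`, `z`.
#' @export
ideal_helix <- function(p) {
  i <- seq_len(p$n_res) - 1L
  ang <- (p$phase + i * p$twist) * pi / 180
  local <- cbind(p$radius * cos(ang), p$radius * sin(ang), i * p$rise)
  R <- rotation_from_z(p$direction)
  xyz <- t(R %*% t(local)) +
    matrix(p$origin, p$n_res, 3, byrow = TRUE)
  tibble(resno = seq_len(p$n_res), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

ca_atoms_tbl <- function(coords, chain = "A", resno = coords$resno,
                         b = 90, resid = "ALA") {
  tibble(chain = chain, resno = as.integer(resno), icode = "",
         resid = resid, elety = "CA", element = "C",
         x = round(coords$x, 3), y = round(coords$y, 3),
         z = round(coords$z, 3),
         occ = 1, b = b, alt = "", polymer = TRUE)
}

#' Terminal-helix hairpin fixture
#'
#' Builds a single chain with an N-terminal and a C-terminal ideal helix at
#' a declared inter-axis angle, with the two anchor C-alphas (first residue
#' of the N-helix, last residue of the C-helix) placed at exactly
#' `separation` angstrom, joined by a non-helical linker, and optionally
#' padded with extended terminal residues that realize terminal offsets.
#' The file-level helix annotation carries the true spans, and the returned
#' model's `manifest` attribute records every expected measurement.
#'
#' @param len_n,len_c Helix lengths in residues (default 12).
#' @param separation Exact anchor-to-anchor distance, angstrom (default 10).
#' @param angle Inter-axis angle, degrees in \[0, 180\] (default 180,
#'   antiparallel).
#' @param loop_len Linker residues between the helices (default 4).
#' @param n_pad,c_pad Extended residues added before/after the helices
#'   (terminal offsets; default 0).
#' @param entry_id Entry identifier.
#' @param b B-factor value written to all atoms (default 90).
#' @param title,keywords Optional metadata written to the header.
#' @param annotate Write the true helix spans as annotation (default TRUE).
#' @return A `structure_model` with a one-row `manifest` attribute
#'   (`hairpin_manifest()` columns).
#' @export
helix_hairpin <- function(len_n = 12L, len_c = 12L, separation = 10,
                          angle = 180, loop_len = 4L, n_pad = 0L,
                          c_pad = 0L, entry_id = "HPIN", b = 90,
                          title = NA_character_, keywords = character(0),
                          annotate = TRUE) {
  stopifnot(len_n >= 1, len_c >= 1, angle >= 0, angle <= 180,
            loop_len >= 0, n_pad >= 0, c_pad >= 0)
  if (separation <= 0) {
    hf_config_error("hairpin separation must be positive (distinct anchors)")
  }
  th <- angle * pi / 180
  d1 <- c(0, 0, 1)
  d2 <- c(sin(th), 0, cos(th))
  hx_n <- ideal_helix(helix_params(len_n, direction = d1))
  hx_c0 <- ideal_helix(helix_params(len_c, direction = d2))
  anchor_n <- as.numeric(hx_n[1, c("x", "y", "z")])
  # translate the C-helix so its LAST C-alpha sits exactly `separation`
  # away from the N-helix first C-alpha, offset laterally along +x
  target <- anchor_n + c(separation, 0, 0)
  shift <- target - as.numeric(hx_c0[nrow(hx_c0), c("x", "y", "z")])
  hx_c <- mutate(hx_c0, x = .data$x + shift[1], y = .data$y + shift[2],
                 z = .data$z + shift[3])
  # linker: straight interpolation between the helix ends (non-helical)
  p_from <- as.numeric(hx_n[nrow(hx_n), c("x", "y", "z")])
  p_to <- as.numeric(hx_c[1, c("x", "y", "z")])
  loop <- if (loop_len > 0) {
    f <- seq_len(loop_len) / (loop_len + 1)
    tibble(resno = seq_len(loop_len),
           x = p_from[1] + f * (p_to[1] - p_from[1]),
           y = p_from[2] + f * (p_to[2] - p_from[2]) + 6,  # bulge out
           z = p_from[3] + f * (p_to[3] - p_from[3]))
  } else {
    tibble(resno = integer(0), x = numeric(0), y = numeric(0),
           z = numeric(0))
  }
  pad <- function(n, from, step_dir) {
    if (n == 0) {
      return(tibble(resno = integer(0), x = numeric(0), y = numeric(0),
                    z = numeric(0)))
    }
    k <- seq_len(n)
    tibble(resno = k, x = from[1] + 3.8 * k * step_dir[1],
           y = from[2] + 3.8 * k * step_dir[2],
           z = from[3] + 3.8 * k * step_dir[3])
  }
  pad_n <- pad(n_pad, anchor_n, c(0, -1, 0))
  pad_n <- pad_n[rev(seq_len(nrow(pad_n))), ]   # runs toward the helix
  pad_c <- pad(c_pad, target, c(0, -1, 0))
  coords <- bind_rows(pad_n, hx_n, loop, hx_c, pad_c)
  coords$resno <- seq_len(nrow(coords))
  atoms <- ca_atoms_tbl(coords, b = b)
  n_start <- n_pad + 1L
  n_end <- n_pad + len_n
  c_start <- n_pad + len_n + loop_len + 1L
  c_end <- c_start + len_c - 1L
  helix <- if (annotate) {
    tibble(chain = "A", start = c(n_start, c_start), end = c(n_end, c_end))
  } else {
    empty_helix_tbl()
  }
  manifest <- tibble(entry_id = entry_id, n_res = nrow(coords),
                     n_start = n_start, n_end = n_end, len_n = len_n,
                     c_start = c_start, c_end = c_end, len_c = len_c,
                     n_offset = n_pad, c_offset = c_pad,
                     separation = separation, angle = angle,
                     expected_score = geometry_score(separation, angle))
  md <- empty_metadata()
  md$title <- title
  md$keywords <- keywords
  s <- new_structure_model(atoms, entry_id = entry_id, metadata = md,
                           helix = helix)
  attr(s, "manifest") <- manifest
  s
}

#' Mock predicted fusion model
#'
#' Realizes a construct's chimera as a single ideal helix of the full
#' chain length (numbered 1..n), so both junctions are continuous helices
#' by construction; either junction can be broken by displacing its `k`
#' tag-side residues off the helical curve. The B-factor column carries a
#' confidence profile (scalar or per-residue), and a clash can be planted
#' by adding one tag side-chain atom at an exact distance from a receptor
#' C-alpha.
#'
#' @param construct A one-row `fusion_construct`.
#' @param junction_helical Length-2 logical: keep the N-side / C-side
#'   junction helical (default both TRUE).
#' @param confidence Scalar or per-residue confidence written to the
#'   B-factor column (default 90).
#' @param planted_clash Optional distance (angstrom); plants one tag atom
#'   at exactly this distance from a receptor C-alpha.
#' @param k Number of tag-side residues displaced for a broken junction
#'   (default 4).
#' @return A single-chain `structure_model` of the chimera.
#' @export
fusion_model_fixture <- function(construct, junction_helical = c(TRUE, TRUE),
                                 confidence = 90, planted_clash = NULL,
                                 k = 4L) {
  len <- construct$length
  coords <- ideal_helix(helix_params(len))
  displace <- function(coords, resn) {
    sel <- coords$resno %in% resn
    r <- sqrt(coords$x[sel]^2 + coords$y[sel]^2)
    coords$x[sel] <- coords$x[sel] * (r + 3) / r
    coords$y[sel] <- coords$y[sel] * (r + 3) / r
    coords
  }
  has_tag <- !is.na(construct$tag_start)
  if (!junction_helical[1] && has_tag) {
    coords <- displace(coords, seq(construct$junction_n + 1L,
                                   min(construct$junction_n + k,
                                       construct$tag_end)))
  }
  if (!junction_helical[2] && has_tag) {
    coords <- displace(coords, seq(max(construct$junction_c - k,
                                       construct$tag_start),
                                   construct$junction_c - 1L))
  }
  bvals <- rep_len(confidence, len)
  aa3 <- three_letter(construct$sequence)
  atoms <- ca_atoms_tbl(coords, b = bvals, resid = aa3)
  if (!is.null(planted_clash)) {
    if (!has_tag) hf_config_error("cannot plant a clash without a tag span")
    tag_mid <- as.integer(round((construct$tag_start + construct$tag_end) / 2))
    rec_res <- max(1L, construct$junction_n - 6L)
    p <- coords[coords$resno == rec_res, ]
    radial <- c(p$x, p$y, 0)
    radial <- radial / sqrt(sum(radial^2))
    pos <- c(p$x, p$y, p$z) + planted_clash * radial
    atoms <- bind_rows(atoms, tibble(
      chain = "A", resno = tag_mid, icode = "",
      resid = aa3[tag_mid], elety = "CB", element = "C",
      x = round(pos[1], 3), y = round(pos[2], 3), z = round(pos[3], 3),
      occ = 1, b = bvals[tag_mid], alt = "", polymer = TRUE))
    atoms <- arrange(atoms, .data$resno)
  }
  new_structure_model(atoms, entry_id = paste0("MODEL_", construct$name))
}

three_letter <- function(seq) {
  one <- strsplit(seq, "")[[1]]
  three <- suppressWarnings(bio3d::aa123(one))
  three[is.na(three)] <- "UNK"
  three
}

#' Seeded fixture corpus for screen testing
#'
#' Writes a reproducible mix of planted positive hairpins (all screen
#' criteria satisfied) and negatives that each violate exactly one named
#' criterion (cycling over helix length, terminal offset, separation,
#' angle, excluded keyword), plus a manifest TSV recording the ground
#' truth. Seeded generation is deterministic at the coordinate-text level.
#'
#' @param dir Output directory (created if needed).
#' @param n_files Total number of files (default 10).
#' @param n_positives Number of planted positives (default 3).
#' @param seed RNG seed.
#' @return The manifest tibble (columns: `file`, `entry_id`, `kind`,
#'   `violated`, plus the hairpin geometry truth), invisibly written to
#'   `manifest.tsv` in `dir`.
#' @export
corpus_fixture <- function(dir, n_files = 10L, n_positives = 3L, seed = 7L) {
  if (n_positives > n_files) {
    hf_config_error("n_positives cannot exceed n_files")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  violations <- c("helix_len", "terminal_offset", "separation", "angle",
                  "keywords")
  rows <- list()
  for (i in seq_len(n_files)) {
    eid <- sprintf("SYN%03d", i)
    fname <- sprintf("%s.pdb", tolower(eid))
    positive <- i <= n_positives
    viol <- if (positive) NA_character_ else
      violations[(i - n_positives - 1L) %% length(violations) + 1L]
    arg <- list(len_n = sample(10:14, 1), len_c = sample(10:14, 1),
                separation = sample(seq(6, 14, 0.5), 1),
                angle = sample(seq(165, 180, 1), 1),
                loop_len = sample(3:6, 1),
                n_pad = sample(0:3, 1), c_pad = sample(0:3, 1),
                entry_id = eid, keywords = c("SOLUBLE PROTEIN"))
    if (!positive) {
      arg <- switch(viol,
        helix_len = { arg$len_n <- sample(6:7, 1); arg },
        terminal_offset = { arg$n_pad <- sample(6:8, 1); arg },
        separation = { arg$separation <- sample(seq(20, 25, 0.5), 1); arg },
        angle = { arg$angle <- sample(40:80, 1); arg },
        keywords = { arg$keywords <- c("MEMBRANE PROTEIN"); arg })
    }
    s <- do.call(helix_hairpin, arg)
    write_structure(s, file.path(dir, fname), fmt = "pdb")
    m <- attr(s, "manifest")
    m$file <- fname
    m$kind <- if (positive) "positive" else "negative"
    m$violated <- viol
    rows[[i]] <- m
  }
  manifest <- bind_rows(rows)
  manifest <- manifest[, c("file", "entry_id", "kind", "violated",
                           setdiff(names(manifest),
                                   c("file", "entry_id", "kind", "violated")))]
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}
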