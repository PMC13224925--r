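# Terminal-helix geometry: secondary-structure assignment from C-alpha
# distances, straight-axis fits, inter-helix angles, the end-to-end
# separation and the continuous geometry score used for ranking.

#' Parameters for C-alpha distance-based helix assignment
#'
#' The geometric fallback marks residue i helical when the three forward
#' C-alpha distances d(i,i+2), d(i,i+3) and d(i,i+4) all fall inside
#' conventional alpha-helical windows, and keeps maximal runs of at least
#' `min_run` consecutive helical residues. Used when a file carries no
#' secondary-structure annotation (typically predictor models).
#'
#' @param d13,d14,d15 Length-2 numeric windows (angstrom) for the
#'   C-alpha(i)-C-alpha(i+2), (i+3) and (i+4) distances. Defaults
#'   5.5±0.6, 5.3±0.6 and 6.4±0.7.
#' @param min_run Minimum run length kept as a segment (default 5, one
#'   helical turn plus one residue; must be >= 4).
#' @return A list of class `sse_params`.
#' @export
sse_params <- function(d13 = c(4.9, 6.1), d14 = c(4.7, 5.9),
                       d15 = c(5.7, 7.1), min_run = 5L) {
  stopifnot(length(d13) == 2, length(d14) == 2, length(d15) == 2,
            d13[1] < d13[2], d14[1] < d14[2], d15[1] < d15[2])
  if (min_run < 4) hf_config_error("min_run must be >= 4")
  structure(list(d13 = d13, d14 = d14, d15 = d15,
                 min_run = as.integer(min_run)),
            class = "sse_params")
}

# per-position helical flags; positions are chain indices (not author
# numbers) so that gaps in numbering do not shift the windows -- a real
# chain break produces out-of-window distances and breaks the run anyway
helical_flags <- function(xyz, p) {
  n <- nrow(xyz)
  flags <- rep(FALSE, n)
  if (n < 5) return(flags)
  d <- function(i, j) sqrt(rowSums((xyz[i, , drop = FALSE] -
                                    xyz[j, , drop = FALSE])^2))
  i <- seq_len(n - 4)
  d13 <- d(i, i + 2); d14 <- d(i, i + 3); d15 <- d(i, i + 4)
  ok <- d13 >= p$d13[1] & d13 <= p$d13[2] &
        d14 >= p$d14[1] & d14 <= p$d14[2] &
        d15 >= p$d15[1] & d15 <= p$d15[2]
  ok[is.na(ok)] <- FALSE  # missing C-alpha in a window -> non-helical
  flags[i] <- ok
  flags
}

runs_to_segments <- function(flags, min_run) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  list(start = starts[keep], end = ends[keep])
}

#' Assign helices from C-alpha geometry
#'
#' Distance-based secondary-structure assignment on a C-alpha trace (the
#' annotation-free fallback for predictor models). See [sse_params()] for
#' the rule.
#'
#' @param x A `structure_model` or a C-alpha trace tibble as returned by
#'   [ca_trace()] (columns `resno`, `x`, `y`, `z`).
#' @param chain_id Chain identifier when `x` is a multi-chain structure.
#' @param params An [sse_params()] object.
#' @return Tibble of segments: `chain_id`, `start`, `end` (author
#'   numbering), `length`.
#' @export
assign_helices_geometric <- function(x, chain_id = NULL,
                                     params = sse_params()) {
  if (inherits(x, "structure_model")) {
    chain_id <- resolve_chain(x, chain_id)
    ca <- ca_trace(x, chain_id)
  } else {
    ca <- x
    chain_id <- chain_id %||% "A"
  }
  if (nrow(ca) < 5) {
    hf_data_error("geometric assignment needs a chain of >= 5 residues")
  }
  flags <- helical_flags(as.matrix(ca[, c("x", "y", "z")]), params)
  seg <- runs_to_segments(flags, params$min_run)
  tibble(chain_id = rep(chain_id, length(seg$start)),
         start = ca$resno[seg$start], end = ca$resno[seg$end],
         length = seg$end - seg$start + 1L)
}

#' Fit a straight axis through a helix segment
#'
#' Principal-direction fit to the segment's C-alpha coordinates; the axis is
#' oriented N-to-C (flipped if needed so that it points from the first
#' toward the last C-alpha).
#'
#' @param ca C-alpha trace tibble of the chain ([ca_trace()]).
#' @param start,end First and last author residue numbers of the segment.
#' @return An `axis_fit` list: `centroid`, unit `direction`, `rmsd_to_axis`
#'   (root-mean-square perpendicular distance of the C-alphas to the fitted
#'   line, angstrom) and `n_atoms`.
#' @export
fit_helix_axis <- function(ca, start, end) {
  sel <- ca$resno >= start & ca$resno <= end & !is.na(ca$x)
  xyz <- as.matrix(ca[sel, c("x", "y", "z")])
  if (nrow(xyz) < 4) {
    hf_data_error(sprintf(
      "segment %d-%d has %d C-alpha atoms; axis fit needs >= 4",
      start, end, nrow(xyz)))
  }
  centroid <- colMeans(xyz)
  cc <- sweep(xyz, 2, centroid)
  dir <- svd(cc, nu = 0, nv = 1)$v[, 1]
  ends <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(dir * ends) < 0) dir <- -dir
  proj <- cc %*% dir
  perp2 <- rowSums(cc^2) - proj^2
  structure(list(centroid = centroid, direction = as.numeric(dir),
                 rmsd_to_axis = sqrt(mean(pmax(perp2, 0))),
                 n_atoms = nrow(xyz)),
            class = "axis_fit")
}

#' Angle between two helix axes
#'
#' Direction-aware angle between N-to-C axis vectors, in degrees within
#' \[0, 180\]; antiparallel helices give ~180 degrees.
#'
#' @param a,b `axis_fit` objects (or unit 3-vectors).
#' @return Angle in degrees.
#' @export
inter_helix_angle <- function(a, b) {
  va <- if (inherits(a, "axis_fit")) a$direction else a
  vb <- if (inherits(b, "axis_fit")) b$direction else b
  d <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Terminal C-alpha separation of a helix pair
#'
#' Euclidean distance between the C-alpha of the first residue of the
#' N-terminal helix and the C-alpha of the last residue of the C-terminal
#' helix -- the two atoms that would splice onto the receptor's TM5 and TM6.
#'
#' @param ca C-alpha trace of the chain.
#' @param n_start Author number of the N-helix first residue.
#' @param c_end Author number of the C-helix last residue.
#' @return Distance in angstrom.
#' @export
terminal_separation <- function(ca, n_start, c_end) {
  p1 <- ca[match(n_start, ca$resno), c("x", "y", "z")]
  p2 <- ca[match(c_end, ca$resno), c("x", "y", "z")]
  if (any(is.na(p1))) {
    hf_data_error(sprintf("residue %d has no C-alpha anchor", n_start))
  }
  if (any(is.na(p2))) {
    hf_data_error(sprintf("residue %d has no C-alpha anchor", c_end))
  }
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
}

#' Locate and measure the terminal helix pair of a chain
#'
#' Takes the N-terminal-most and C-terminal-most helix segments and checks
#' the screen's hard placement gates: both helices at least `min_len`
#' residues long, the first starting within `max_offset` residues of the
#' chain N-terminus and the last ending within `max_offset` residues of the
#' C-terminus, and the two being distinct segments. Geometry (axes, angle,
#' separation) is measured whenever computable, even for failing chains, so
#' every gate outcome can be reported.
#'
#' @param ca C-alpha trace of the chain ([ca_trace()]).
#' @param helices Segment tibble ([annotated_helices()] or
#'   [assign_helices_geometric()]), sorted N-to-C.
#' @param min_len Minimum helix length in residues (default 8).
#' @param max_offset Maximum separation from the chain terminus in residues
#'   (default 5).
#' @return One-row tibble: `ok`, `reason` (`NA` or one of `no_helix`,
#'   `single_helix`, `too_short_N`, `too_short_C`, `offset_N`, `offset_C`),
#'   segment bounds and lengths, `n_offset`, `c_offset`, `separation`
#'   (angstrom), `angle` (degrees).
#' @export
terminal_helices <- function(ca, helices, min_len = 8L, max_offset = 5L) {
  na_row <- tibble(ok = FALSE, reason = NA_character_,
                   n_start = NA_integer_, n_end = NA_integer_,
                   n_len = NA_integer_, c_start = NA_integer_,
                   c_end = NA_integer_, c_len = NA_integer_,
                   n_offset = NA_integer_, c_offset = NA_integer_,
                   separation = NA_real_, angle = NA_real_)
  if (nrow(helices) == 0) { na_row$reason <- "no_helix"; return(na_row) }
  helices <- arrange(helices, .data$start)
  nh <- helices[1, ]
  ch <- helices[nrow(helices), ]
  out <- na_row
  out$n_start <- nh$start; out$n_end <- nh$end; out$n_len <- nh$length
  out$c_start <- ch$start; out$c_end <- ch$end; out$c_len <- ch$length
  out$n_offset <- match(nh$start, ca$resno) - 1L
  out$c_offset <- nrow(ca) - match(ch$end, ca$resno)
  distinct_pair <- nrow(helices) >= 2 &&
    !(nh$start == ch$start && nh$end == ch$end)
  # measure geometry whenever both segments support an axis fit
  if (distinct_pair) {
    geom <- tryCatch({
      ax_n <- fit_helix_axis(ca, nh$start, nh$end)
      ax_c <- fit_helix_axis(ca, ch$start, ch$end)
      list(sep = terminal_separation(ca, nh$start, ch$end),
           ang = inter_helix_angle(ax_n, ax_c))
    }, hf_error = function(e) NULL)
    if (!is.null(geom)) { out$separation <- geom$sep; out$angle <- geom$ang }
  }
  reasons <- c(
    single_helix = !distinct_pair,
    too_short_N  = nh$length < min_len,
    too_short_C  = ch$length < min_len,
    offset_N     = out$n_offset > max_offset,
    offset_C     = out$c_offset > max_offset)
  if (any(reasons)) {
    out$reason <- names(reasons)[which(reasons)[1]]
  } else {
    out$ok <- TRUE
  }
  out
}

#' Continuous geometry score for a terminal-helix pair
#'
#' Ranks candidate tags by how close their terminal-helix geometry is to the
#' screen's target: an end-to-end separation near `target_separation` and
#' axes near antiparallel. The score is
#' `max(0, 1 - |sep - d0| / halfwidth) * max(0, (angle - min_angle) / (180 -
#' min_angle))`, reaching 1 exactly at `sep = d0`, `angle = 180`.
#'
#' @param separation Terminal C-alpha separation, angstrom (>= 0).
#' @param angle Inter-helix angle, degrees in \[0, 180\].
#' @param target_separation Ideal separation `d0` (default 10).
#' @param separation_halfwidth Distance at which the separation factor
#'   reaches zero (default 8).
#' @param min_angle Angle at and below which the angle factor is zero
#'   (default 90).
#' @return Score in \[0, 1\]; vectorized over `separation` and `angle`.
#' @export
geometry_score <- function(separation, angle, target_separation = 10,
                           separation_halfwidth = 8, min_angle = 90) {
  stopifnot(separation_halfwidth > 0, min_angle < 180)
  sep_term <- pmax(0, 1 - abs(separation - target_separation) /
                        separation_halfwidth)
  ang_term <- pmax(0, (angle - min_angle) / (180 - min_angle))
  sep_term * ang_term
}
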