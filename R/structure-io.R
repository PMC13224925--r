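# Reading and writing PDB / mmCIF files.
#
# Coordinate parsing is delegated to bio3d (read.pdb / read.cif); this file
# adds the policies the screen needs on top: model-1-only, deterministic
# alternate-location resolution (highest occupancy, ties broken
# alphabetically), polymer/het classification, and a light header scan for
# the curation metadata (TITLE, KEYWDS, REMARK 350 assembly size, SOURCE
# organism and their mmCIF counterparts) that bio3d does not expose.

#' Read a protein structure
#'
#' Reads a PDB or mmCIF file into an atom-level tibble. Only model 1 of
#' multi-model files is retained; alternate locations are resolved to the
#' highest-occupancy atom (ties broken by the alphabetically first altloc
#' id) so repeated reads of the same file are byte-reproducible downstream;
#' hydrogens are kept as read. Entry metadata (title, keywords, deposited
#' assembly size, source organism) is populated where the header carries it
#' and left `NA`/"unknown" otherwise.
#'
#' @param path Path to a structure file.
#' @param fmt `"pdb"`, `"mmcif"`, or `"auto"` (extension-based; `.cif` /
#'   `.mmcif` are mmCIF, everything else PDB).
#' @return A `structure_model` tibble (one row per atom) carrying
#'   `entry_id`, `metadata` and annotated `helix` spans as attributes.
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_structure(helix_hairpin(), pdb)
#' s <- read_structure(pdb)
#' chains(s)
read_structure <- function(path, fmt = c("auto", "pdb", "mmcif")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) hf_io_error(sprintf("file not found: %s", path))
  if (fmt == "auto") {
    fmt <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (fmt == "pdb") {
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    },
    error = function(e) {
      hf_parse_error(sprintf("cannot parse %s file '%s': %s",
                             fmt, path, conditionMessage(e)))
    })
  atoms <- as_tibble(raw$atom)
  if (fmt == "mmcif" && !is.null(atoms$segid)) {
    # bio3d's cif reader stores the model number in segid; keep model 1 only
    first_model <- atoms$segid[1]
    atoms <- atoms[is.na(atoms$segid) | atoms$segid == first_model, ]
  }
  atoms <- tibble(
    chain   = as.character(atoms$chain),
    resno   = as.integer(atoms$resno),
    icode   = ifelse(is.na(atoms$insert), "", as.character(atoms$insert)),
    resid   = as.character(atoms$resid),
    elety   = as.character(atoms$elety),
    element = ifelse(is.na(atoms$elesy), "", as.character(atoms$elesy)),
    x = atoms$x, y = atoms$y, z = atoms$z,
    occ = ifelse(is.na(atoms$o), 1, atoms$o),
    b   = ifelse(is.na(atoms$b), 0, atoms$b),
    alt = ifelse(is.na(atoms$alt), "", as.character(atoms$alt)),
    type = as.character(atoms$type))
  atoms$chain[is.na(atoms$chain)] <- "A"
  atoms <- resolve_altlocs(atoms)
  atoms$polymer <- atoms$type == "ATOM" |
    (atoms$type == "HETATM" & atoms$resid %in% MOD_POLYMER_AA)
  atoms$polymer[atoms$resid %in% WATER_RESIDUES] <- FALSE
  atoms$type <- NULL
  if (!any(atoms$polymer)) {
    hf_data_error(sprintf("'%s' contains no polymer chains", path))
  }
  hdr <- if (fmt == "pdb") scan_pdb_header(path) else scan_cif_header(path)
  eid <- hdr$entry_id %||% toupper(sub("\\.[^.]*$", "", basename(path)))
  new_structure_model(atoms, entry_id = eid, metadata = hdr$metadata,
                      helix = hdr$helix)
}

# highest occupancy wins; ties go to the alphabetically first altloc id
resolve_altlocs <- function(atoms) {
  if (all(atoms$alt == "")) return(atoms)
  atoms |>
    group_by(.data$chain, .data$resno, .data$icode, .data$elety) |>
    arrange(desc(.data$occ), .data$alt, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange_file_order(atoms)
}

# restore original file order after a grouped operation
arrange_file_order <- function(sub, full) {
  key <- function(d) paste(d$chain, d$resno, d$icode, d$elety, d$alt)
  sub[order(match(key(sub), key(full))), ]
}

scan_pdb_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- function(tag) lines[startsWith(lines, tag)]
  strip <- function(x, from) trimws(substring(x, from))
  title <- rec("TITLE ")
  title <- if (length(title)) paste(strip(title, 11), collapse = " ") else NA_character_
  kw <- rec("KEYWDS")
  keywords <- if (length(kw)) {
    trimws(strsplit(paste(strip(kw, 11), collapse = " "), ",")[[1]])
  } else character(0)
  src <- rec("SOURCE")
  organism <- NA_character_
  hit <- grep("ORGANISM_SCIENTIFIC:", src, value = TRUE)
  if (length(hit)) {
    organism <- trimws(sub(";.*$", "", sub(".*ORGANISM_SCIENTIFIC:", "", hit[1])))
  }
  helix_lines <- rec("HELIX")
  helix <- if (length(helix_lines)) {
    tibble(chain = trimws(substr(helix_lines, 20, 20)),
           start = as.integer(substr(helix_lines, 22, 25)),
           end   = as.integer(substr(helix_lines, 34, 37)))
  } else empty_helix_tbl()
  list(entry_id = NULL,
       metadata = list(title = title, keywords = keywords,
                       oligomer_count = biomt_chain_count(lines),
                       organism = organism),
       helix = helix)
}

# deposited-assembly size from REMARK 350 of biomolecule 1:
# (#chains listed) x (#BIOMT operators); NA when the record is absent
biomt_chain_count <- function(lines) {
  r350 <- lines[startsWith(lines, "REMARK 350")]
  if (!length(r350)) return(NA_integer_)
  bio_starts <- grep("BIOMOLECULE:", r350)
  if (length(bio_starts) > 1) r350 <- r350[seq_len(bio_starts[2] - 1)]
  ch <- grep("APPLY THE FOLLOWING TO CHAINS:", r350, value = TRUE)
  if (!length(ch)) return(NA_integer_)
  ids <- unlist(strsplit(sub(".*CHAINS:", "", paste(ch, collapse = ",")), ","))
  ids <- unique(trimws(ids))
  ids <- ids[nzchar(ids)]
  ops <- grep("^REMARK 350   BIOMT1", r350)
  n_ops <- max(1L, length(ops))
  as.integer(length(ids) * n_ops)
}

scan_cif_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entry_id <- NULL
  db <- grep("^data_", lines, value = TRUE)
  if (length(db)) entry_id <- toupper(sub("^data_", "", db[1]))
  grab <- function(tag) {
    hit <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    val <- trimws(sub(paste0("^", tag, "\\s+"), "", hit[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  title <- grab("_struct.title")
  kw <- grab("_struct_keywords.text")
  keywords <- if (!is.na(kw)) trimws(strsplit(kw, ",")[[1]]) else character(0)
  olig <- suppressWarnings(as.integer(grab("_pdbx_struct_assembly.oligomeric_count")))
  organism <- grab("_entity_src_gen.pdbx_gene_src_scientific_name")
  if (is.na(organism)) organism <- grab("_entity_src_nat.pdbx_organism_scientific")
  list(entry_id = entry_id,
       metadata = list(title = title, keywords = keywords,
                       oligomer_count = olig, organism = organism),
       helix = scan_cif_struct_conf(lines))
}

# minimal _struct_conf reader: helix spans only (HELX* conf_type_id)
scan_cif_struct_conf <- function(lines) {
  loops <- grep("^loop_", lines)
  for (l0 in loops) {
    i <- l0 + 1
    fields <- character(0)
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      fields <- c(fields, trimws(lines[i])); i <- i + 1
    }
    if (!any(startsWith(fields, "_struct_conf."))) next
    rows <- list()
    while (i <= length(lines) && !startsWith(trimws(lines[i]), "_") &&
           !startsWith(trimws(lines[i]), "loop_") &&
           !startsWith(trimws(lines[i]), "#") && nzchar(trimws(lines[i]))) {
      rows[[length(rows) + 1]] <- scan(text = lines[i], what = "character",
                                       quiet = TRUE)
      i <- i + 1
    }
    if (!length(rows)) return(empty_helix_tbl())
    m <- do.call(rbind, rows)
    colnames(m) <- sub("^_struct_conf\\.", "", fields)
    keep <- grepl("^HELX", m[, "conf_type_id"])
    m <- m[keep, , drop = FALSE]
    if (!nrow(m)) return(empty_helix_tbl())
    return(tibble(chain = m[, "beg_auth_asym_id"],
                  start = as.integer(m[, "beg_auth_seq_id"]),
                  end   = as.integer(m[, "end_auth_seq_id"])))
  }
  empty_helix_tbl()
}

#' Annotated helix spans of one chain
#'
#' Returns the helix segments recorded in the file's secondary-structure
#' annotation (PDB `HELIX` records or the mmCIF `_struct_conf` category),
#' clipped to residues actually present in the coordinates. An empty tibble
#' means the file carries no annotation and callers should fall back to
#' geometric assignment ([assign_helices_geometric()]).
#'
#' @param s A `structure_model`.
#' @param chain_id Chain identifier.
#' @return Tibble with columns `chain_id`, `start`, `end`, `length`
#'   (author numbering), sorted by `start`.
#' @export
annotated_helices <- function(s, chain_id = NULL) {
  chain_id <- resolve_chain(s, chain_id)
  hx <- attr(s, "helix") %||% empty_helix_tbl()
  hx <- hx[hx$chain == chain_id, , drop = FALSE]
  present <- ca_trace(s, chain_id)$resno
  out <- purrr::pmap_dfr(hx, function(chain, start, end) {
    inside <- present[present >= start & present <= end]
    if (!length(inside)) return(NULL)
    tibble(chain_id = chain, start = min(inside), end = max(inside),
           length = length(inside))
  })
  if (!nrow(out)) {
    return(tibble(chain_id = character(0), start = integer(0),
                  end = integer(0), length = integer(0)))
  }
  arrange(out, .data$start)
}

#' Remove waters and non-polymer heteroatoms
#'
#' Drops water molecules (HOH/WAT/DOD) and all non-polymer het entities
#' (ligands, ions) while leaving polymer residues untouched, including
#' modified amino acids such as MSE. Idempotent.
#'
#' @param s A `structure_model`.
#' @return A `structure_model` containing only polymer atoms.
#' @export
strip_nonpolymer <- function(s) {
  out <- s[s$polymer, ]
  new_structure_model(out, entry_id = entry_id(s),
                      metadata = structure_metadata(s),
                      helix = attr(s, "helix"))
}

#' Write a structure to PDB or mmCIF
#'
#' Writes atom records plus the annotated helix spans and title/keyword
#' metadata carried by the object, so that
#' `read_structure(write_structure(s))` reproduces chain ids, author
#' numbering, annotation and coordinates to fixed-width precision (1e-3
#' angstrom in the PDB dialect).
#'
#' @param s A `structure_model`.
#' @param path Output file path.
#' @param fmt `"pdb"`, `"mmcif"`, or `"auto"` (from the extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, fmt = c("auto", "pdb", "mmcif")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (nrow(s) == 0) hf_data_error("refusing to write an empty structure")
  lines <- if (fmt == "pdb") format_pdb(s) else format_mmcif(s)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) hf_io_error(sprintf("cannot write '%s'", path))
  invisible(path)
}

format_pdb <- function(s) {
  if (max(s$resno) > 9999 || nrow(s) > 99999) {
    hf_data_error(paste("structure exceeds fixed-width PDB limits",
                        "(resno > 9999 or > 99999 atoms); write mmCIF instead"))
  }
  md <- structure_metadata(s)
  out <- character(0)
  if (!is.na(md$title)) out <- c(out, sprintf("TITLE     %s", md$title))
  if (length(md$keywords)) {
    out <- c(out, sprintf("KEYWDS    %s", paste(md$keywords, collapse = ", ")))
  }
  hx <- attr(s, "helix") %||% empty_helix_tbl()
  if (nrow(hx)) {
    res_at <- function(chain, no) {
      r <- s$resid[s$chain == chain & s$resno == no]
      if (length(r)) r[1] else "ALA"
    }
    for (i in seq_len(nrow(hx))) {
      out <- c(out, sprintf(
        "HELIX  %3d %3d %3s %1s %4d  %3s %1s %4d  1%30s%6d",
        i, i, res_at(hx$chain[i], hx$start[i]), hx$chain[i], hx$start[i],
        res_at(hx$chain[i], hx$end[i]), hx$chain[i], hx$end[i], "",
        hx$end[i] - hx$start[i] + 1L))
    }
  }
  serial <- seq_len(nrow(s))
  name4 <- ifelse(nchar(s$elety) >= 4, substr(s$elety, 1, 4),
                  sprintf("%-3s", s$elety))
  name4 <- ifelse(nchar(s$elety) >= 4, name4, paste0(" ", name4))
  rectype <- ifelse(s$polymer, "ATOM  ", "HETATM")
  atom_lines <- sprintf(
    "%6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rectype, serial, name4, substr(paste0(s$alt, " "), 1, 1),
    sprintf("%3s", s$resid), s$chain, s$resno,
    substr(paste0(s$icode, " "), 1, 1),
    s$x, s$y, s$z, s$occ, s$b, s$element)
  # TER after each chain's last atom
  out2 <- character(0)
  for (ch in unique(s$chain)) {
    out2 <- c(out2, atom_lines[s$chain == ch], "TER")
  }
  c(out, out2, "END")
}

format_mmcif <- function(s) {
  md <- structure_metadata(s)
  out <- c(sprintf("data_%s", entry_id(s)), "#")
  if (!is.na(md$title)) out <- c(out, sprintf("_struct.title '%s'", md$title), "#")
  if (length(md$keywords)) {
    out <- c(out, sprintf("_struct_keywords.text '%s'",
                          paste(md$keywords, collapse = ", ")), "#")
  }
  if (!is.na(md$oligomer_count)) {
    out <- c(out, sprintf("_pdbx_struct_assembly.oligomeric_count %d",
                          md$oligomer_count), "#")
  }
  hx <- attr(s, "helix") %||% empty_helix_tbl()
  if (nrow(hx)) {
    out <- c(out, "loop_",
             "_struct_conf.id", "_struct_conf.conf_type_id",
             "_struct_conf.beg_auth_asym_id", "_struct_conf.beg_auth_seq_id",
             "_struct_conf.end_auth_asym_id", "_struct_conf.end_auth_seq_id",
             sprintf("HELX%d HELX_P %s %d %s %d", seq_len(nrow(hx)),
                     hx$chain, hx$start, hx$chain, hx$end),
             "#")
  }
  out <- c(out, "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  grp <- ifelse(s$polymer, "ATOM", "HETATM")
  out <- c(out, sprintf(
    "%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    grp, seq_len(nrow(s)),
    ifelse(nzchar(s$element), s$element, "C"), s$elety,
    ifelse(nzchar(s$alt), s$alt, "."), s$resid, s$chain, s$resno,
    ifelse(nzchar(s$icode), s$icode, "?"),
    s$x, s$y, s$z, s$occ, s$b, s$resno, s$resid, s$chain, s$elety), "#")
  out
}
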