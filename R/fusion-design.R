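# Chimera design: splice a tag into a receptor in place of ICL3 over a
# matrix of entry/exit junction points, and write the construct sequences.
#
# Entry/exit semantics: entry = author number of the LAST retained receptor
# residue on the TM5 side, exit = FIRST retained residue on the TM6 side,
# so replacing ICL3 residues 235-244 is entry 234 / exit 245.

#' A numbered protein sequence
#'
#' A one-letter sequence carrying the author number of its first residue,
#' so receptor residues can be addressed by the numbering used in
#' structures and in the literature (numbering is assumed contiguous).
#'
#' @param id Sequence identifier.
#' @param seq One-letter amino-acid string (standard letters plus X).
#' @param first_auth Author number of the first residue (default 1).
#' @return A one-row tibble of class `numbered_sequence` with columns
#'   `id`, `seq`, `first_auth`, `last_auth`.
#' @export
numbered_sequence <- function(id, seq, first_auth = 1L) {
  seq <- toupper(gsub("\\s", "", seq))
  if (nchar(seq) && grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", seq)) {
    hf_data_error(sprintf("sequence '%s' contains non-amino-acid letters", id))
  }
  structure(tibble(id = id, seq = seq,
                   first_auth = as.integer(first_auth),
                   last_auth = as.integer(first_auth) + nchar(seq) - 1L),
            class = c("numbered_sequence", class(tibble())))
}

#' Read numbered sequences from FASTA
#'
#' Headers may carry a `first=<n>` token declaring the author number of the
#' first residue (default 1), e.g. `>A2AR first=2`.
#'
#' @param path FASTA file.
#' @return A list of [numbered_sequence()] objects, named by id.
#' @export
read_numbered_fasta <- function(path) {
  if (!file.exists(path)) hf_io_error(sprintf("FASTA not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) hf_data_error(sprintf("no records in %s", path))
  out <- lapply(seq_along(set), function(i) {
    hdr <- names(set)[i]
    id <- strsplit(hdr, "\\s+")[[1]][1]
    first <- 1L
    m <- regmatches(hdr, regexpr("first=\\d+", hdr))
    if (length(m) && nzchar(m)) first <- as.integer(sub("first=", "", m))
    numbered_sequence(id, as.character(set[[i]]), first)
  })
  setNames(out, vapply(out, function(x) x$id, character(1)))
}

subseq_auth <- function(ns, from, to) {
  if (from > to) return("")
  substr(ns$seq, from - ns$first_auth + 1L, to - ns$first_auth + 1L)
}

# mutations: either a tibble/data.frame with columns pos, new, or a
# character vector like "R72S" (original residue checked when given)
normalize_mutations <- function(mutations) {
  if (is.null(mutations)) return(NULL)
  if (is.character(mutations)) {
    m <- regmatches(mutations, regexec("^([A-Z]?)(\\d+)([A-Z])$", mutations))
    bad <- vapply(m, length, integer(1)) == 0
    if (any(bad)) {
      hf_config_error(sprintf("cannot parse mutation(s): %s",
                              paste(mutations[bad], collapse = ", ")))
    }
    return(tibble(orig = vapply(m, `[`, "", 2),
                  pos = as.integer(vapply(m, `[`, "", 3)),
                  new = vapply(m, `[`, "", 4)))
  }
  m <- as_tibble(mutations)
  if (!all(c("pos", "new") %in% names(m))) {
    hf_config_error("mutation table needs columns pos, new")
  }
  if (is.null(m$orig)) m$orig <- ""
  m[, c("orig", "pos", "new")]
}

apply_tag_mutations <- function(tag, mutations) {
  mut <- normalize_mutations(mutations)
  if (is.null(mut)) return(tag$seq)
  seq <- tag$seq
  for (i in seq_len(nrow(mut))) {
    k <- mut$pos[i] - tag$first_auth + 1L
    if (k < 1 || k > nchar(seq)) {
      hf_config_error(sprintf(
        "mutation position %d outside tag %s (residues %d-%d)",
        mut$pos[i], tag$id, tag$first_auth, tag$last_auth))
    }
    if (nzchar(mut$orig[i]) && substr(seq, k, k) != mut$orig[i]) {
      hf_config_error(sprintf(
        "mutation %s%d%s: tag %s has %s at position %d",
        mut$orig[i], mut$pos[i], mut$new[i], tag$id, substr(seq, k, k),
        mut$pos[i]))
    }
    substr(seq, k, k) <- mut$new[i]
  }
  seq
}

#' Splice a tag into a receptor
#'
#' Builds the chimera `receptor[first..entry] + tag + receptor[exit..last]`,
#' deleting receptor residues `entry+1 .. exit-1` (the loop being replaced).
#' Optional tag mutations (e.g. `"R72S"`) are applied before splicing and
#' each changes exactly one tag position.
#'
#' @param receptor A [numbered_sequence()].
#' @param tag A [numbered_sequence()] or plain sequence string (may be
#'   empty, giving an identity splice when `exit == entry + 1`).
#' @param entry Author number of the last retained receptor residue before
#'   the tag.
#' @param exit Author number of the first retained receptor residue after
#'   the tag.
#' @param mutations Optional tag mutations (character like `"R72S"`, or a
#'   data frame with columns `pos`, `new`).
#' @param name Construct name; default `receptor_tag_eENTRY_xEXIT`.
#' @return A one-row `fusion_construct` tibble: `name`, `sequence`,
#'   `junction_n` / `junction_c` (chimera positions of the last receptor
#'   residue before and first after the tag), `tag_start` / `tag_end`
#'   (chimera positions of the tag span), `deleted_start` / `deleted_end`
#'   (receptor author numbers removed; `NA` for an identity splice),
#'   `entry`, `exit`, ids and lengths.
#' @export
splice_sequence <- function(receptor, tag, entry, exit, mutations = NULL,
                            name = NULL) {
  if (!inherits(tag, "numbered_sequence")) {
    tag <- numbered_sequence("tag", tag)
  }
  if (entry >= exit) {
    hf_config_error(sprintf(
      "entry (%d) must precede exit (%d)", entry, exit))
  }
  if (entry < receptor$first_auth || exit > receptor$last_auth) {
    hf_config_error(sprintf(
      "junctions %d/%d outside receptor %s numbering %d-%d",
      entry, exit, receptor$id, receptor$first_auth, receptor$last_auth))
  }
  tag_seq <- apply_tag_mutations(tag, mutations)
  n_seg <- subseq_auth(receptor, receptor$first_auth, entry)
  c_seg <- subseq_auth(receptor, exit, receptor$last_auth)
  chimera <- paste0(n_seg, tag_seq, c_seg)
  name <- name %||% sprintf("%s_%s_e%d_x%d", receptor$id, tag$id, entry, exit)
  jn <- nchar(n_seg)
  structure(tibble(
    name = name,
    sequence = chimera,
    length = nchar(chimera),
    junction_n = jn,
    junction_c = jn + nchar(tag_seq) + 1L,
    tag_start = if (nchar(tag_seq)) jn + 1L else NA_integer_,
    tag_end = if (nchar(tag_seq)) jn + nchar(tag_seq) else NA_integer_,
    deleted_start = if (exit - entry > 1) entry + 1L else NA_integer_,
    deleted_end = if (exit - entry > 1) exit - 1L else NA_integer_,
    entry = as.integer(entry), exit = as.integer(exit),
    receptor_id = receptor$id, tag_id = tag$id,
    tag_length = nchar(tag_seq)),
    class = c("fusion_construct", class(tibble())))
}

#' Default entry/exit candidates flanking an ICL3 span
#'
#' Given the receptor span to be replaced (the declared ICL3), proposes
#' `n_entries` entry points starting at the last residue before the span
#' and stepping inward (into the loop), and `n_exits` exit points starting
#' at the first residue after the span and stepping inward. The pair
#' (span_start - 1, span_end + 1) -- the construct that replaces exactly
#' the declared span -- is always included.
#'
#' @param icl3_start,icl3_end Author numbers of the replaced span.
#' @param n_entries,n_exits Number of candidates per side (default 5).
#' @return List with integer vectors `entries` and `exits` (ascending).
#' @export
icl3_candidates <- function(icl3_start, icl3_end, n_entries = 5L,
                            n_exits = 5L) {
  if (icl3_start > icl3_end) hf_config_error("icl3_start must be <= icl3_end")
  entries <- seq(icl3_start - 1L, by = 1L, length.out = n_entries)
  exits <- sort(seq(icl3_end + 1L, by = -1L, length.out = n_exits))
  if (max(entries) >= min(exits)) {
    hf_config_error("entry/exit candidates overlap; shrink the counts or span")
  }
  list(entries = as.integer(entries), exits = as.integer(exits))
}

#' Enumerate the entry/exit construct matrix
#'
#' One construct per valid `(entry, exit)` pair (entry < exit); invalid
#' pairs are skipped and counted in the `skipped_pairs` attribute. Output
#' order is deterministic (entry ascending, then exit ascending) and names
#' are unique over (receptor, tag, entry, exit).
#'
#' @param receptor,tag [numbered_sequence()] objects.
#' @param entries,exits Integer vectors of candidate junction points
#'   (author numbers), e.g. from [icl3_candidates()].
#' @param mutations Optional tag mutations applied to every construct.
#' @return A `fusion_construct` tibble, one row per construct.
#' @export
enumerate_constructs <- function(receptor, tag, entries, exits,
                                 mutations = NULL) {
  if (!length(entries) || !length(exits)) {
    hf_config_error("entry and exit candidate lists must be non-empty")
  }
  grid <- tidyr::expand_grid(entry = sort(unique(as.integer(entries))),
                             exit = sort(unique(as.integer(exits))))
  valid <- grid$entry < grid$exit
  if (!any(valid)) {
    hf_config_error("all entry/exit pairs are invalid (entry >= exit)")
  }
  out <- purrr::pmap_dfr(grid[valid, ], function(entry, exit) {
    splice_sequence(receptor, tag, entry, exit, mutations)
  })
  structure(out,
            skipped_pairs = sum(!valid),
            class = c("fusion_construct", class(tibble())))
}

#' Write constructs to FASTA
#'
#' One record per construct; the header is the construct name followed by a
#' parsable junction descriptor (`entry=.. exit=.. tag=a..b`), and
#' sequences are wrapped at 60 columns. Constructs containing `X` residues
#' are written verbatim with a warning.
#'
#' @param constructs A `fusion_construct` tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_constructs_fasta <- function(constructs, path) {
  if (!nrow(constructs)) hf_data_error("no constructs to write")
  if (anyDuplicated(constructs$name)) {
    hf_data_error(sprintf("duplicate construct names: %s",
                          paste(unique(constructs$name[
                            duplicated(constructs$name)]), collapse = ", ")))
  }
  if (any(grepl("X", constructs$sequence, fixed = TRUE))) {
    warn("some constructs contain 'X' residues; written verbatim")
  }
  set <- Biostrings::AAStringSet(constructs$sequence)
  names(set) <- sprintf("%s entry=%d exit=%d tag=%s..%s",
                        constructs$name, constructs$entry, constructs$exit,
                        constructs$tag_start, constructs$tag_end)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a construct FASTA written by [write_constructs_fasta()]
#'
#' @param path FASTA path.
#' @return Tibble with `name`, `entry`, `exit`, `tag_start`, `tag_end`,
#'   `sequence`.
#' @export
read_construct_fasta <- function(path) {
  if (!file.exists(path)) hf_io_error(sprintf("FASTA not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  hdr <- names(set)
  grab_int <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=-?[0-9NA]+"), hdr))
    suppressWarnings(as.integer(sub(paste0(key, "="), "", m)))
  }
  tg <- regmatches(hdr, regexpr("tag=[0-9NA]+\\.\\.[0-9NA]+", hdr))
  tg <- sub("tag=", "", tg)
  tibble(name = vapply(strsplit(hdr, "\\s+"), `[`, "", 1),
         entry = grab_int("entry"),
         exit = grab_int("exit"),
         tag_start = suppressWarnings(as.integer(sub("\\.\\..*", "", tg))),
         tag_end = suppressWarnings(as.integer(sub(".*\\.\\.", "", tg))),
         sequence = unname(as.character(set)))
}

#' Manifest TSV for a set of constructs
#'
#' @param constructs A `fusion_construct` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_construct_manifest <- function(constructs, path) {
  readr::write_tsv(as_tibble(constructs) |> select(-"sequence"), path)
  invisible(path)
}
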