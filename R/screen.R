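# Corpus screening: per-chain geometry gates, metadata curation flags and
# the ranked candidate table.

#' Screening criteria
#'
#' Bundle of thresholds for the terminal-helix screen. Geometry defaults
#' implement the standard ICL3 fusion-tag mining rules: terminal helices of at least eight
#' residues within five residues of the chain termini, near-antiparallel
#' axes, and a terminal C-alpha separation near 10 angstrom. The keyword and
#' oligomer filters automate the curation step that removes membrane,
#' homo-oligomeric and designed proteins; metadata the file does not carry
#' is flagged `"unknown"`, never silently passed or failed.
#'
#' @param min_helix_len Minimum terminal-helix length, residues (default 8).
#' @param max_terminal_offset Maximum separation of a terminal helix from
#'   its chain terminus, residues (default 5).
#' @param target_separation Target terminal C-alpha separation, angstrom
#'   (default 10).
#' @param separation_halfwidth Half-width of the accepted separation window
#'   around the target, angstrom (default 8, i.e. 2-18 accepted).
#' @param min_angle Hard antiparallelity gate, degrees (default 140; the
#'   continuous score uses its own softer 90-degree floor).
#' @param require_single_polymer_chain If `TRUE`, entries with more than one
#'   polymer chain fail the `single_chain` flag.
#' @param exclude_keywords Lowercase substrings that disqualify an entry
#'   when found in its title or keywords.
#' @return A list of class `screen_criteria`.
#' @export
screen_criteria <- function(min_helix_len = 8L, max_terminal_offset = 5L,
                            target_separation = 10, separation_halfwidth = 8,
                            min_angle = 140,
                            require_single_polymer_chain = FALSE,
                            exclude_keywords = c("membrane", "micelle",
                                                 "de novo", "designed")) {
  if (min_helix_len <= 0 || max_terminal_offset < 0 ||
      target_separation <= 0 || separation_halfwidth <= 0 ||
      min_angle <= 0 || min_angle > 180) {
    hf_config_error("screen_criteria thresholds must be positive (min_angle in (0,180])")
  }
  structure(list(min_helix_len = as.integer(min_helix_len),
                 max_terminal_offset = as.integer(max_terminal_offset),
                 target_separation = target_separation,
                 separation_halfwidth = separation_halfwidth,
                 min_angle = min_angle,
                 require_single_polymer_chain = isTRUE(require_single_polymer_chain),
                 exclude_keywords = tolower(exclude_keywords)),
            class = "screen_criteria")
}

GEOMETRY_FLAGS <- c("pass_helix_len", "pass_terminal_offset",
                    "pass_separation", "pass_angle")
METADATA_FLAGS <- c("pass_keywords", "pass_oligomer")
ALL_FLAGS <- c(GEOMETRY_FLAGS, "pass_single_chain", METADATA_FLAGS)

#' Screen one chain against the geometry criteria
#'
#' Applies the mining pipeline to a single chain: strip non-polymer
#' entities, retrieve helices (file annotation when present, geometric
#' fallback otherwise -- the method used is recorded), locate the terminal
#' pair, apply the length/offset/separation/angle gates and compute the
#' geometry score. Every gate outcome is recorded even after the first
#' failure, whenever it is computable; the score is present only when all
#' hard gates pass. Metadata flags are initialized `"unknown"` and filled by
#' [apply_metadata_filters()].
#'
#' @param s A `structure_model`.
#' @param chain_id Chain identifier.
#' @param criteria A [screen_criteria()] object.
#' @param sse [sse_params()] for the geometric fallback.
#' @return A one-row candidate tibble.
#' @export
screen_chain <- function(s, chain_id = NULL, criteria = screen_criteria(),
                         sse = sse_params()) {
  chain_id <- resolve_chain(s, chain_id)
  s <- strip_nonpolymer(s)
  helices <- annotated_helices(s, chain_id)
  helix_source <- "annotation"
  ca <- ca_trace(s, chain_id)
  if (nrow(helices) == 0) {
    helix_source <- "geometric"
    helices <- if (nrow(ca) >= 5 && sum(!is.na(ca$x)) >= 5) {
      assign_helices_geometric(ca, chain_id, sse)
    } else {
      helices
    }
  }
  th <- terminal_helices(ca, helices, criteria$min_helix_len,
                         criteria$max_terminal_offset)
  flag <- function(cond) {
    ifelse(is.na(cond), "unknown", ifelse(cond, "pass", "fail"))
  }
  pair_found <- !th$reason %in% c("no_helix", "single_helix")
  rec <- tibble(
    entry_id = entry_id(s),
    chain_id = chain_id,
    n_res = nrow(ca),
    helix_source = helix_source,
    n_start = th$n_start, n_end = th$n_end, n_len = th$n_len,
    c_start = th$c_start, c_end = th$c_end, c_len = th$c_len,
    n_offset = th$n_offset, c_offset = th$c_offset,
    separation = th$separation, angle = th$angle,
    pass_terminal_pair = flag(pair_found),
    pass_helix_len = if (!pair_found) "fail" else
      flag(th$n_len >= criteria$min_helix_len &
           th$c_len >= criteria$min_helix_len),
    pass_terminal_offset = if (!pair_found) "fail" else
      flag(th$n_offset <= criteria$max_terminal_offset &
           th$c_offset <= criteria$max_terminal_offset),
    pass_separation = flag(abs(th$separation - criteria$target_separation) <=
                             criteria$separation_halfwidth),
    pass_angle = flag(th$angle >= criteria$min_angle),
    pass_single_chain = if (!criteria$require_single_polymer_chain) "pass"
      else flag(length(chains(s)) == 1L),
    pass_keywords = "unknown",
    pass_oligomer = "unknown",
    thermophile = "unknown",
    known_binder = "unknown",
    reason = th$reason)
  hard <- c(rec$pass_terminal_pair, rec$pass_helix_len,
            rec$pass_terminal_offset, rec$pass_separation, rec$pass_angle,
            rec$pass_single_chain)
  rec$score <- if (all(hard == "pass") && !is.na(rec$separation)) {
    geometry_score(rec$separation, rec$angle,
                   criteria$target_separation, criteria$separation_halfwidth)
  } else {
    NA_real_
  }
  rec
}

#' Apply metadata-based curation filters to candidate records
#'
#' Automates the deterministic part of the curation step: excluded keywords
#' found in the entry title or keyword list fail the `keywords` flag, a
#' deposited assembly of more than one chain fails the `oligomer` flag, and
#' missing metadata leaves the flag `"unknown"` without touching the
#' geometry flags. An optional annotation table (columns `entry_id`,
#' `thermophile`, `known_binder`) merges prioritization labels for
#' thermophilic origin and known protein binders. Any metadata `"fail"`
#' withdraws the score.
#'
#' @param records Candidate tibble from [screen_chain()].
#' @param metadata A metadata list ([structure_metadata()]); ignored when
#'   `records` spans several entries and `annotations` carries the lookup.
#' @param criteria A [screen_criteria()] object.
#' @param annotations Optional annotation data frame or TSV path.
#' @return The records with metadata flags and annotations filled in.
#' @export
apply_metadata_filters <- function(records, metadata = NULL,
                                   criteria = screen_criteria(),
                                   annotations = NULL) {
  if (!is.null(metadata)) {
    text <- tolower(paste(c(metadata$title, metadata$keywords),
                          collapse = " "))
    known_text <- !is.na(metadata$title) || length(metadata$keywords) > 0
    hit <- any(vapply(criteria$exclude_keywords, grepl, logical(1),
                      x = text, fixed = TRUE))
    records$pass_keywords <- if (!known_text) "unknown"
      else if (hit) "fail" else "pass"
    oc <- metadata$oligomer_count
    records$pass_oligomer <- if (is.na(oc)) "unknown"
      else if (oc > 1) "fail" else "pass"
  }
  if (!is.null(annotations)) {
    ann <- read_annotation_table(annotations)
    i <- match(records$entry_id, ann$entry_id)
    records$thermophile <- ifelse(is.na(i), "unknown", ann$thermophile[i])
    records$known_binder <- ifelse(is.na(i), "unknown", ann$known_binder[i])
  }
  meta_fail <- records$pass_keywords == "fail" |
    records$pass_oligomer == "fail"
  records$score[meta_fail] <- NA_real_
  records
}

read_annotation_table <- function(annotations) {
  ann <- if (is.character(annotations)) {
    if (!file.exists(annotations)) {
      hf_io_error(sprintf("annotation table not found: %s", annotations))
    }
    readr::read_tsv(annotations, comment = "#", show_col_types = FALSE)
  } else {
    as_tibble(annotations)
  }
  need <- c("entry_id", "thermophile", "known_binder")
  if (!all(need %in% names(ann))) {
    hf_config_error(sprintf(
      "annotation table must have columns %s (missing: %s)",
      paste(need, collapse = ", "),
      paste(setdiff(need, names(ann)), collapse = ", ")))
  }
  bad <- setdiff(unique(c(ann$thermophile, ann$known_binder)),
                 c("yes", "no", "unknown"))
  if (length(bad)) {
    hf_config_error(sprintf(
      "annotation values must be yes/no/unknown (got: %s)",
      paste(bad, collapse = ", ")))
  }
  ann
}

#' Screen a corpus of structure files
#'
#' Runs [screen_chain()] plus [apply_metadata_filters()] over every polymer
#' chain of every readable file and returns the ranked candidate table.
#' Unreadable files are counted and reported, never fatal. Ranking is by
#' score descending with a deterministic `(entry_id, chain_id)` tie-break,
#' and is invariant under input file order.
#'
#' @param paths Character vector of PDB/mmCIF files, or a directory.
#' @param criteria A [screen_criteria()] object.
#' @param annotations Optional annotation table (see
#'   [apply_metadata_filters()]).
#' @param sse [sse_params()] for annotation-free chains.
#' @return A `screen_report` tibble (one row per chain) with the criteria,
#'   input counts and failed files attached as attributes.
#' @export
screen_corpus <- function(paths, criteria = screen_criteria(),
                          annotations = NULL, sse = sse_params()) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif|mmcif)$",
                        full.names = TRUE)
  }
  if (!length(paths)) hf_io_error("no input structure files")
  failed <- character(0)
  recs <- list()
  for (p in sort(paths)) {
    s <- tryCatch(read_structure(p), error = function(e) {
      inform(sprintf("skipping unreadable file %s: %s", p,
                     conditionMessage(e)))
      NULL
    })
    if (is.null(s)) { failed <- c(failed, p); next }
    for (ch in chains(s)) {
      rec <- screen_chain(s, ch, criteria, sse)
      rec <- apply_metadata_filters(rec, structure_metadata(s), criteria,
                                    annotations)
      recs[[length(recs) + 1]] <- rec
    }
  }
  if (!length(recs)) hf_io_error("no readable structure files in corpus")
  out <- bind_rows(recs) |>
    arrange(desc(!is.na(.data$score)), desc(.data$score),
            .data$entry_id, .data$chain_id)
  structure(out,
            criteria = criteria,
            n_input = length(paths),
            n_failed = length(failed),
            failed_files = failed,
            class = c("screen_report", class(tibble())))
}

#' Write a screen report as TSV
#'
#' The body is a plain TSV; run metadata (tool version, criteria, input
#' counts) goes into `#`-prefixed header lines, so repeated runs on the same
#' corpus produce byte-identical files.
#'
#' @param report A `screen_report` from [screen_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  crit <- attr(report, "criteria")
  hdr <- c(
    sprintf("# helixfuse screen report (helixfuse %s)",
            as.character(packageVersion("helixfuse"))),
    sprintf("# criteria: %s", deparse1(unclass(crit))),
    sprintf("# input_files: %d  unreadable: %d",
            attr(report, "n_input") %||% NA, attr(report, "n_failed") %||% 0))
  ok <- tryCatch({
    writeLines(hdr, path)
    readr::write_tsv(as_tibble(report), path, append = TRUE,
                     col_names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) hf_io_error(sprintf("cannot write report to '%s'", path))
  invisible(path)
}

#' @export
tidy.screen_report <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.screen_report <- function(x, ...) {
  geom_pass <- rowSums(sapply(c(GEOMETRY_FLAGS, "pass_terminal_pair"),
                              function(f) x[[f]] == "pass")) ==
    length(GEOMETRY_FLAGS) + 1
  tibble(n_chains = nrow(x),
         n_files = attr(x, "n_input") %||% NA_integer_,
         n_unreadable = attr(x, "n_failed") %||% 0L,
         n_geometry_pass = sum(geom_pass),
         n_scored = sum(!is.na(x$score)),
         best_score = if (any(!is.na(x$score))) max(x$score, na.rm = TRUE)
                      else NA_real_)
}

#' Plot a screen report
#'
#' Separation-versus-angle scatter of all screened chains, colored by
#' whether the chain passed every geometry gate, with the acceptance window
#' and the score target marked.
#'
#' @param object A `screen_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, ...) {
  crit <- attr(object, "criteria") %||% screen_criteria()
  df <- as_tibble(object) |>
    filter(!is.na(.data$separation), !is.na(.data$angle)) |>
    mutate(outcome = ifelse(!is.na(.data$score), "pass", "fail"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$separation, y = .data$angle,
                                   colour = .data$outcome)) +
    ggplot2::annotate("rect",
                      xmin = crit$target_separation - crit$separation_halfwidth,
                      xmax = crit$target_separation + crit$separation_halfwidth,
                      ymin = crit$min_angle, ymax = 180,
                      alpha = 0.08, fill = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = crit$target_separation,
                        linetype = "dashed") +
    ggplot2::labs(x = "terminal C-alpha separation (Å)",
                  y = "inter-helix angle (°)",
                  colour = "geometry gates") +
    ggplot2::theme_minimal()
}
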