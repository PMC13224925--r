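# Atom-level structure container
#
# A `structure_model` is a tibble with one row per atom (after alternate-
# location resolution) and the columns
#   chain, resno, icode, resid, elety, element, x, y, z, occ, b, alt, polymer
# plus attributes:
#   entry_id  - identifier of the entry (file stem or data block name)
#   metadata  - list(title, keywords, oligomer_count, organism)
#   helix     - tibble(chain, start, end) of annotated helix spans, as read
#
# Residues are identified throughout by author numbering plus insertion code;
# internal row indices never appear in outputs.  Only model 1 of multi-model
# files is retained and B-factors are carried verbatim, so predictor models
# with per-residue confidence (pLDDT, 0-100) in the B-factor column work
# unchanged.

# non-water residues that are chemically modified amino acids and must stay
# in the polymer even when deposited as HETATM
MOD_POLYMER_AA <- c("MSE", "SEP", "TPO", "PTR", "CSO", "MLY", "HYP", "KCX",
                    "CME", "CSD", "PCA", "FME")

WATER_RESIDUES <- c("HOH", "WAT", "DOD")

new_structure_model <- function(atoms, entry_id = "UNKNOWN",
                                metadata = empty_metadata(),
                                helix = empty_helix_tbl()) {
  atoms <- as_tibble(atoms)
  structure(atoms,
            entry_id = entry_id,
            metadata = metadata,
            helix = helix,
            class = c("structure_model", class(tibble())))
}

empty_metadata <- function() {
  list(title = NA_character_, keywords = character(0),
       oligomer_count = NA_integer_, organism = NA_character_)
}

empty_helix_tbl <- function() {
  tibble(chain = character(0), start = integer(0), end = integer(0))
}

#' Entry identifier of a structure
#' @param s A `structure_model`.
#' @return A length-one character vector.
#' @export
entry_id <- function(s) attr(s, "entry_id") %||% "UNKNOWN"

#' Entry-level metadata of a structure
#' @param s A `structure_model`.
#' @return A list with elements `title`, `keywords`, `oligomer_count` and
#'   `organism`; unknown fields are `NA` (never silently guessed).
#' @export
structure_metadata <- function(s) attr(s, "metadata") %||% empty_metadata()

#' @export
print.structure_model <- function(x, ...) {
  ch <- chains(x)
  cat(sprintf("<structure_model> %s: %d atoms, %d chain(s) [%s]\n",
              entry_id(x), nrow(x), length(ch), paste(ch, collapse = ",")))
  NextMethod()
}

#' Polymer chain identifiers of a structure
#' @param s A `structure_model`.
#' @return Character vector of chain ids that contain polymer residues,
#'   in file order.
#' @export
chains <- function(s) {
  unique(s$chain[s$polymer])
}

check_chain <- function(s, chain_id) {
  if (!chain_id %in% s$chain) {
    hf_data_error(sprintf("chain '%s' not found in entry %s (have: %s)",
                          chain_id, entry_id(s),
                          paste(unique(s$chain), collapse = ", ")))
  }
}

#' C-alpha trace of one chain
#'
#' One row per polymer residue in chain order (author numbering preserved);
#' residues lacking a C-alpha atom keep their row with `NA` coordinates so
#' that positional indices still reflect the chain.
#'
#' @param s A `structure_model`.
#' @param chain_id Chain identifier; may be omitted for single-chain models.
#' @return Tibble with columns `resno`, `icode`, `resid`, `aa`, `x`, `y`,
#'   `z`, `b`.
#' @export
ca_trace <- function(s, chain_id = NULL) {
  chain_id <- resolve_chain(s, chain_id)
  # distinct() keeps first-appearance (file) order, which is the polymer order
  res <- s |>
    filter(.data$chain == chain_id, .data$polymer) |>
    distinct(.data$resno, .data$icode, .keep_all = TRUE) |>
    select("resno", "icode", "resid")
  cas <- s |>
    filter(.data$chain == chain_id, .data$polymer, .data$elety == "CA") |>
    select("resno", "icode", "x", "y", "z", "b")
  out <- left_join(as_tibble(res), as_tibble(cas), by = c("resno", "icode"))
  out$aa <- aa_one_letter(out$resid)
  out <- out[, c("resno", "icode", "resid", "aa", "x", "y", "z", "b")]
  class(out) <- class(tibble())
  out
}

resolve_chain <- function(s, chain_id) {
  if (is.null(chain_id)) {
    ch <- chains(s)
    if (length(ch) != 1L) {
      hf_data_error(sprintf(
        "entry %s has %d polymer chains; chain_id must be given",
        entry_id(s), length(ch)))
    }
    return(ch)
  }
  check_chain(s, chain_id)
  chain_id
}

#' One-letter sequence of a chain
#' @inheritParams ca_trace
#' @return Length-one character string; non-standard residues are mapped to
#'   their parent amino acid, unknowns to `"X"`.
#' @export
model_sequence <- function(s, chain_id = NULL) {
  paste(ca_trace(s, chain_id)$aa, collapse = "")
}

aa_one_letter <- function(resid) {
  one <- suppressWarnings(bio3d::aa321(resid))
  one[is.na(one) | !one %in% c(LETTERS)] <- "X"
  one
}
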