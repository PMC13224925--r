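# Triage of predicted fusion models: junction helical continuity,
# junction confidence (pLDDT read from the B-factor column), least-squares
# superposition onto a reference receptor conformation, and inter-domain
# heavy-atom clash detection.
#
# Predicted chimera models are assumed renumbered 1..n, matching chimera
# sequence positions; reference structures keep their own author numbering
# and are aligned through an explicit residue mapping.

#' Locate the two junction windows of a fusion model
#'
#' Windows of `k` receptor-side plus `k` tag-side residues centered on the
#' two splice points recorded in the construct. The model must be a single
#' chain whose sequence matches the construct sequence exactly; windows
#' running off a short flanking segment are clipped with a warning.
#'
#' @param model A single-chain `structure_model` of the predicted chimera
#'   (residues numbered 1..n).
#' @param construct The matching one-row `fusion_construct`.
#' @param k Window half-width in residues (default 4, about one helical
#'   turn per side).
#' @return Tibble with one row per junction: `junction` (`"N"`/`"C"`),
#'   `start`, `end` (chimera positions), `n_res`.
#' @export
locate_junctions <- function(model, construct, k = 4L) {
  seq_model <- model_sequence(model)
  if (!identical(seq_model, construct$sequence)) {
    n <- min(nchar(seq_model), nchar(construct$sequence))
    a <- strsplit(seq_model, "")[[1]]
    b <- strsplit(construct$sequence, "")[[1]]
    mis <- which(a[seq_len(n)] != b[seq_len(n)])
    where <- if (length(mis)) {
      sprintf("first mismatch at position %d (model %s vs construct %s)",
              mis[1], a[mis[1]], b[mis[1]])
    } else {
      sprintf("lengths differ (model %d vs construct %d)",
              nchar(seq_model), nchar(construct$sequence))
    }
    hf_data_error(sprintf(
      "model %s does not match construct %s: %s",
      entry_id(model), construct$name, where))
  }
  len <- nchar(seq_model)
  clip <- function(v) pmin(pmax(v, 1L), len)
  jn <- construct$junction_n
  jc <- construct$junction_c
  w <- tibble(junction = c("N", "C"),
              start = as.integer(c(jn - k + 1L, jc - k)),
              end = as.integer(c(jn + k, jc + k - 1L)))
  clipped <- w$start < 1L | w$end > len
  w$start <- clip(w$start); w$end <- clip(w$end)
  if (any(clipped)) {
    warn(sprintf("junction window(s) %s clipped to the chain",
                 paste(w$junction[clipped], collapse = ",")))
  }
  w$n_res <- w$end - w$start + 1L
  w
}

#' Helical fraction of a junction window
#'
#' Fraction of window residues assigned helical by the geometric
#' secondary-structure rule run on the whole model chain; 1.0 means the
#' splice is a continuous helix across the junction.
#'
#' @param model Single-chain `structure_model`.
#' @param window One row of [locate_junctions()] output (or any tibble with
#'   `start`/`end` chimera positions).
#' @param sse [sse_params()].
#' @return Fraction in \[0, 1\].
#' @export
junction_helicity <- function(model, window, sse = sse_params()) {
  seg <- assign_helices_geometric(model, params = sse)
  resn <- seq.int(window$start[1], window$end[1])
  helical <- unlist(purrr::map2(seg$start, seg$end, seq.int))
  mean(resn %in% helical)
}

#' Mean confidence across a junction window
#'
#' Arithmetic mean of the per-residue confidence (C-alpha B-factor column,
#' predictor convention 0-100) over the window residues; residues without a
#' C-alpha are dropped from the mean.
#'
#' @inheritParams junction_helicity
#' @return Mean confidence (0-100 for pLDDT-bearing models).
#' @export
junction_confidence <- function(model, window) {
  ca <- ca_trace(model)
  sel <- ca$resno >= window$start[1] & ca$resno <= window$end[1]
  b <- ca$b[sel & !is.na(ca$b) & !is.na(ca$x)]
  if (!length(b)) hf_data_error("junction window has no C-alpha atoms")
  if (all(b == 0)) {
    warn("all B-factor values are zero; model may not carry confidences")
  }
  mean(b)
}

# Kabsch: optimal proper rotation aligning P onto Q (n x 3 matrices),
# with the sign (reflection) guard on the smallest singular vector
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cq - as.numeric(R %*% cp)
  Pfit <- t(R %*% t(P)) + matrix(t_vec, nrow(P), 3, byrow = TRUE)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((Pfit - Q)^2))))
}

#' Residue mapping between a model and a reference
#'
#' Pairs model residues with reference residues by author-number identity
#' after applying a declared numbering `offset`
#' (`ref_resno = model_resno + offset`), optionally restricted to residue
#' spans of the model. Only pairs where both members have a C-alpha are
#' kept; a requested span residue missing from either side is an error,
#' never a silent drop.
#'
#' @param model,reference `structure_model` objects.
#' @param spans Optional list of `c(start, end)` model-numbering spans to
#'   map (default: all shared residues).
#' @param offset Numbering offset added to model residue numbers.
#' @param model_chain,ref_chain Chain ids (default: the single chain).
#' @return Tibble with columns `model_resno`, `ref_resno`.
#' @export
residue_mapping <- function(model, reference, spans = NULL, offset = 0L,
                            model_chain = NULL, ref_chain = NULL) {
  cam <- ca_trace(model, model_chain)
  car <- ca_trace(reference, ref_chain)
  cam <- cam[!is.na(cam$x), ]
  car <- car[!is.na(car$x), ]
  if (is.null(spans)) {
    mres <- intersect(cam$resno, car$resno - offset)
  } else {
    mres <- unlist(lapply(spans, function(sp) seq.int(sp[1], sp[2])))
    missing_m <- setdiff(mres, cam$resno)
    missing_r <- setdiff(mres + offset, car$resno)
    if (length(missing_m) || length(missing_r)) {
      hf_data_error(sprintf(
        "mapping spans reference residues absent from %s",
        if (length(missing_m)) "the model" else "the reference"))
    }
  }
  tibble(model_resno = as.integer(sort(mres)),
         ref_resno = as.integer(sort(mres) + offset))
}

#' Superpose a model onto a reference
#'
#' Least-squares rigid-body superposition (optimal rotation from the SVD of
#' the coordinate cross-covariance, with a reflection guard) of the model
#' C-alphas onto the reference C-alphas over a residue mapping, as used to
#' check that a fusion model preserves the receptor's (inactive-state)
#' conformation.
#'
#' @param model,reference `structure_model` objects.
#' @param mapping Tibble with `model_resno`, `ref_resno`
#'   ([residue_mapping()]); built over all shared residues when `NULL`.
#' @param model_chain,ref_chain Chain ids (default: the single chain).
#' @return A `superposition` list: `rmsd` (angstrom, after superposition),
#'   `rotation` (3x3), `translation` (length 3), `n` (pairs used).
#' @export
superpose_to_reference <- function(model, reference, mapping = NULL,
                                   model_chain = NULL, ref_chain = NULL) {
  if (is.null(mapping)) {
    mapping <- residue_mapping(model, reference,
                               model_chain = model_chain,
                               ref_chain = ref_chain)
  }
  cam <- ca_trace(model, model_chain)
  car <- ca_trace(reference, ref_chain)
  im <- match(mapping$model_resno, cam$resno)
  ir <- match(mapping$ref_resno, car$resno)
  keep <- !is.na(im) & !is.na(ir) & !is.na(cam$x[im]) & !is.na(car$x[ir])
  if (sum(keep) < 3) {
    hf_data_error("superposition needs at least 3 mapped C-alpha pairs")
  }
  P <- as.matrix(cam[im[keep], c("x", "y", "z")])
  Q <- as.matrix(car[ir[keep], c("x", "y", "z")])
  fit <- kabsch(P, Q)
  structure(list(rmsd = fit$rmsd, rotation = fit$rotation,
                 translation = fit$translation, n = sum(keep)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d C-alpha pairs, RMSD %.3f Å\n", x$n, x$rmsd))
  invisible(x)
}

#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n = x$n)
}

#' Inter-domain steric clashes
#'
#' All heavy-atom pairs with one atom in the tag domain and one in the
#' receptor domain closer than `cutoff` (default 3.0 angstrom, well below
#' van der Waals contact so hits are unambiguous potential clashes), with
#' pairs fewer than 3 residues apart in the chain excluded as bonded
#' neighborhood. Sorted by distance ascending.
#'
#' @param model Single-chain `structure_model`.
#' @param tag_span `c(start, end)` residue numbers of the tag domain.
#' @param receptor_spans List of `c(start, end)` receptor spans.
#' @param cutoff Distance cutoff in angstrom.
#' @return Tibble of contacts: tag-atom residue/name, receptor-atom
#'   residue/name, `distance`.
#' @export
interdomain_clashes <- function(model, tag_span, receptor_spans,
                                cutoff = 3.0) {
  if (!is.list(receptor_spans)) receptor_spans <- list(receptor_spans)
  spans <- c(list(tag_span), receptor_spans)
  for (i in seq_along(spans)) {
    for (j in seq_len(i - 1L)) {
      if (spans[[i]][1] <= spans[[j]][2] && spans[[j]][1] <= spans[[i]][2]) {
        hf_data_error("tag and receptor spans overlap")
      }
    }
  }
  heavy <- model[model$polymer & !model$element %in% c("H", "D") &
                   !is.na(model$x), ]
  in_span <- function(resno, sp) resno >= sp[1] & resno <= sp[2]
  tag_at <- heavy[in_span(heavy$resno, tag_span), ]
  rec_at <- heavy[Reduce(`|`, lapply(receptor_spans, in_span,
                                     resno = heavy$resno)), ]
  empty <- tibble(tag_resno = integer(0), tag_atom = character(0),
                  receptor_resno = integer(0), receptor_atom = character(0),
                  distance = numeric(0))
  if (!nrow(tag_at) || !nrow(rec_at)) return(empty)
  d2 <- outer(rowSums(tag_at[, c("x", "y", "z")]^2),
              rowSums(rec_at[, c("x", "y", "z")]^2), `+`) -
    2 * as.matrix(tag_at[, c("x", "y", "z")]) %*%
      t(as.matrix(rec_at[, c("x", "y", "z")]))
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  out <- tibble(
    tag_resno = tag_at$resno[hit[, 1]],
    tag_atom = tag_at$elety[hit[, 1]],
    receptor_resno = rec_at$resno[hit[, 2]],
    receptor_atom = rec_at$elety[hit[, 2]],
    distance = sqrt(pmax(d2[hit], 0)))
  out <- out[abs(out$tag_resno - out$receptor_resno) >= 3L, ]
  arrange(out, .data$distance)
}

#' Assess one predicted fusion model
#'
#' Runs the four junction/conformation checks -- helical continuity and
#' mean confidence at both junction windows, C-alpha RMSD to a reference
#' receptor conformation, and inter-domain clash detection -- and returns a
#' one-row report with the composite ranking key used to pick one construct
#' per tag: continuous junctions first, then fewer clashes, then higher
#' mean junction confidence, then lower RMSD.
#'
#' @param model Single-chain `structure_model` of the predicted chimera.
#' @param construct Matching `fusion_construct` row.
#' @param reference Optional reference `structure_model` (e.g. the inactive
#'   receptor conformation); RMSD is `NA` when absent.
#' @param mapping Optional [residue_mapping()] for the superposition; by
#'   default the receptor spans of the chimera are mapped by author-number
#'   identity shifted by `ref_offset`.
#' @param ref_offset Numbering offset from chimera positions to reference
#'   numbering (reference resno = chimera position + offset over the
#'   N-terminal receptor segment).
#' @param k Junction window half-width (default 4).
#' @param clash_cutoff Heavy-atom clash cutoff, angstrom (default 3.0).
#' @param sse [sse_params()].
#' @return One-row `assessment` tibble.
#' @export
assess_model <- function(model, construct, reference = NULL, mapping = NULL,
                         ref_offset = 0L, k = 4L, clash_cutoff = 3.0,
                         sse = sse_params()) {
  w <- locate_junctions(model, construct, k)
  wn <- w[w$junction == "N", ]
  wc <- w[w$junction == "C", ]
  hel_n <- junction_helicity(model, wn, sse)
  hel_c <- junction_helicity(model, wc, sse)
  conf_n <- junction_confidence(model, wn)
  conf_c <- junction_confidence(model, wc)
  len <- construct$length
  has_tag <- !is.na(construct$tag_start)
  clash <- if (has_tag) {
    interdomain_clashes(model, c(construct$tag_start, construct$tag_end),
                        list(c(1L, construct$junction_n),
                             c(construct$junction_c, len)),
                        clash_cutoff)
  } else {
    interdomain_clashes(model, c(1L, 0L), list(c(1L, len)), clash_cutoff)[0, ]
  }
  rmsd <- NA_real_
  if (!is.null(reference)) {
    if (is.null(mapping)) {
      spans <- list(c(1L, construct$junction_n))
      if (construct$junction_c <= len) {
        spans <- c(spans, list(c(construct$junction_c, len)))
      }
      # chimera C-segment position p corresponds to receptor residue
      # p + offset + (deleted + tag length difference); map the two receptor
      # segments separately
      n_map <- tibble(model_resno = seq.int(1L, construct$junction_n),
                      ref_resno = seq.int(1L, construct$junction_n) +
                        as.integer(ref_offset))
      shift_c <- construct$exit - construct$junction_c
      c_map <- tibble(model_resno = seq.int(construct$junction_c, len),
                      ref_resno = seq.int(construct$junction_c, len) +
                        as.integer(shift_c))
      mapping <- bind_rows(n_map, c_map)
    }
    rmsd <- superpose_to_reference(model, reference, mapping)$rmsd
  }
  structure(tibble(
    name = construct$name,
    helicity_n = hel_n, helicity_c = hel_c,
    continuous_n = hel_n == 1, continuous_c = hel_c == 1,
    conf_n = conf_n, conf_c = conf_c,
    rmsd_to_reference = rmsd,
    clash_count = nrow(clash),
    clashes = list(clash)),
    class = c("assessment", class(tibble())))
}

#' Rank assessed models
#'
#' Deterministic composite ordering: both junctions continuous first, then
#' clash count ascending, then mean junction confidence descending, then
#' RMSD ascending, with construct name as the final stable tie-break.
#'
#' @param reports Assessment tibble (rows from [assess_model()]).
#' @return The tibble sorted, with a `rank` column prepended.
#' @export
rank_assessments <- function(reports) {
  out <- reports |>
    mutate(.continuous = .data$continuous_n & .data$continuous_c,
           .conf = (.data$conf_n + .data$conf_c) / 2) |>
    arrange(desc(.data$.continuous), .data$clash_count, desc(.data$.conf),
            .data$rmsd_to_reference, .data$name) |>
    select(-".continuous", -".conf")
  out$rank <- seq_len(nrow(out))
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' @export
tidy.assessment <- function(x, ...) {
  as_tibble(x) |> select(-"clashes")
}

#' Plot assessed models
#'
#' Clash count against mean junction confidence, with junction continuity
#' mapped to shape, for comparing candidate constructs at a glance.
#'
#' @param object An assessment tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assessment <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(conf = (.data$conf_n + .data$conf_c) / 2,
           continuous = ifelse(.data$continuous_n & .data$continuous_c,
                               "continuous", "broken"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conf, y = .data$clash_count,
                                   shape = .data$continuous,
                                   label = .data$name)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "mean junction confidence",
                  y = "inter-domain clashes",
                  shape = "junction helicity") +
    ggplot2::theme_minimal()
}
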