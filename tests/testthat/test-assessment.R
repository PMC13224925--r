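# Junction triage: windows, helicity, confidence, superposition, clashes.

make_construct <- function(tag_len = 30) {
  splice_sequence(demo_receptor(), demo_tag(tag_len), 234, 245)
}

test_that("junction windows straddle the recorded splice points", {
  con <- make_construct()
  model <- fusion_model_fixture(con)
  w <- locate_junctions(model, con, k = 4)
  expect_equal(w$n_res, c(8, 8))
  expect_equal(w$start[w$junction == "N"], con$junction_n - 3)
  expect_equal(w$end[w$junction == "N"], con$junction_n + 4)
  expect_equal(w$start[w$junction == "C"], con$junction_c - 4)
  expect_equal(w$end[w$junction == "C"], con$junction_c + 3)
  # oversized window clips with a warning
  con2 <- splice_sequence(numbered_sequence("R", strrep("A", 20)),
                          "DDDDD", 3, 10)
  m2 <- fusion_model_fixture(con2)
  expect_warning(w2 <- locate_junctions(m2, con2, k = 6), "clipped")
  expect_equal(w2$start[w2$junction == "N"], 1)
  # model/construct mismatch names the first discrepancy
  bad <- con
  bad$sequence <- paste0("G", substr(con$sequence, 2, con$length))
  expect_error(locate_junctions(model, bad, k = 4), "position 1",
               class = "hf_data_error")
  bad2 <- con
  bad2$sequence <- paste0(con$sequence, "A")
  expect_error(locate_junctions(model, bad2, k = 4), "lengths differ",
               class = "hf_data_error")
})

test_that("junction helicity equals the brute-force window fraction", {
  con <- make_construct()
  for (jh in list(c(TRUE, TRUE), c(FALSE, TRUE), c(TRUE, FALSE))) {
    model <- fusion_model_fixture(con, junction_helical = jh)
    w <- locate_junctions(model, con)
    ca <- ca_trace(model)
    flags <- oracle_helical_flags(as.matrix(ca[, c("x", "y", "z")]))
    seg <- oracle_segments(flags, 5)
    helical <- unlist(mapply(seq, seg$start, seg$end, SIMPLIFY = FALSE))
    for (j in c("N", "C")) {
      wj <- w[w$junction == j, ]
      expect_equal(junction_helicity(model, wj),
                   mean(seq(wj$start, wj$end) %in% ca$resno[helical]),
                   info = paste(jh, collapse = ","))
    }
  }
  # continuous fixture is fully helical at both junctions; broken is not
  cont <- fusion_model_fixture(con)
  w <- locate_junctions(cont, con)
  expect_equal(junction_helicity(cont, w[w$junction == "N", ]), 1.0)
  expect_equal(junction_helicity(cont, w[w$junction == "C", ]), 1.0)
  broken <- fusion_model_fixture(con, junction_helical = c(TRUE, FALSE))
  expect_lt(junction_helicity(broken, w[w$junction == "C", ]), 1.0)
  expect_equal(junction_helicity(broken, w[w$junction == "N", ]), 1.0)
})

test_that("junction confidence averages the B-factor column", {
  con <- make_construct()
  m90 <- fusion_model_fixture(con, confidence = 90)
  w <- locate_junctions(m90, con)
  expect_equal(junction_confidence(m90, w[1, ]), 90)
  # half 90 / half 50 across the N window -> 70
  prof <- rep(90, con$length)
  prof[(con$junction_n + 1):con$length] <- 50
  mix <- fusion_model_fixture(con, confidence = prof)
  wn <- w[w$junction == "N", ]
  expect_equal(junction_confidence(mix, wn), 70)
  # a residue without C-alpha drops out of the mean
  tb <- tibble::as_tibble(mix)
  tb <- tb[!(tb$resno == con$junction_n & tb$elety == "CA"), ]
  m3 <- helixfuse:::new_structure_model(tb, entry_id = "DROP")
  expect_equal(junction_confidence(m3, wn), mean(c(rep(90, 3), rep(50, 4))))
  # all-zero B-factors warn
  z <- fusion_model_fixture(con, confidence = 0)
  expect_warning(junction_confidence(z, wn), "zero")
})

test_that("superposition is exact for copies and rigid motions", {
  con <- make_construct()
  model <- fusion_model_fixture(con)
  ref <- model
  expect_equal(superpose_to_reference(model, ref)$rmsd, 0, tolerance = 1e-9)
  set.seed(17)
  for (i in 1:5) {
    moved <- rotate_model(model, random_rotation(), t = rnorm(3, sd = 30))
    moved <- helixfuse:::new_structure_model(moved, entry_id = "MV")
    fit <- superpose_to_reference(moved, ref)
    expect_equal(fit$rmsd, 0, tolerance = 1e-6)
    # invariance: rmsd(R model + t, ref) == rmsd(model, ref); and symmetry
    expect_equal(superpose_to_reference(ref, moved)$rmsd, fit$rmsd,
                 tolerance = 1e-6)
  }
})

test_that("superposition matches direct minimization and bio3d on noisy pairs", {
  set.seed(23)
  n <- 40
  P <- matrix(rnorm(3 * n, sd = 8), ncol = 3)
  Q <- t(random_rotation() %*% t(P)) +
    matrix(rnorm(3, sd = 5), n, 3, byrow = TRUE) +
    matrix(rnorm(3 * n, sd = 0.3), ncol = 3)   # noise breaks perfect fit
  mk <- function(M) helixfuse:::new_structure_model(tibble::tibble(
    chain = "A", resno = seq_len(nrow(M)), icode = "", resid = "ALA",
    elety = "CA", element = "C", x = M[, 1], y = M[, 2], z = M[, 3],
    occ = 1, b = 0, alt = "", polymer = TRUE))
  fit <- suppressWarnings(
    superpose_to_reference(mk(P), mk(Q)))
  # independent oracle 1: direct numerical minimization over rigid motions
  expect_equal(fit$rmsd, oracle_rmsd(P, Q), tolerance = 1e-3)
  # independent oracle 2: bio3d's least-squares fit
  rb <- bio3d::rmsd(as.numeric(t(Q)), as.numeric(t(P)), fit = TRUE)
  expect_equal(fit$rmsd, rb, tolerance = 1e-3)
  # displacing one of N atoms by 1 A costs ~ sqrt((N-1))/N after refitting
  Q2 <- P
  Q2[5, ] <- Q2[5, ] + c(0, 0, 1) * 0  # start from identical copy
  Q2[5, 3] <- Q2[5, 3] + 1
  fit2 <- superpose_to_reference(mk(P), mk(Q2))
  expect_equal(fit2$rmsd, oracle_rmsd(P, Q2), tolerance = 1e-3)
  # large-cluster closed form sqrt(1/N); refitting recovers a little, so
  # agreement is approximate while the numeric oracle above is exact
  expect_equal(fit2$rmsd, sqrt(1 / n), tolerance = 0.05)
  expect_error(superpose_to_reference(mk(P[1:2, ]), mk(Q[1:2, ])),
               class = "hf_data_error")
})

test_that("superposition never returns a reflection", {
  # a near-planar point set invites a reflected optimum; the guard must
  # keep the rotation proper
  set.seed(5)
  P <- cbind(rnorm(20, sd = 6), rnorm(20, sd = 6), rnorm(20, sd = 1e-4))
  Q <- P
  Q[, 1] <- -Q[, 1]   # mirrored target
  fit <- helixfuse:::kabsch(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("clash detection finds planted contacts and honours the cutoff", {
  con <- make_construct()
  model <- fusion_model_fixture(con, planted_clash = 2.5)
  tag_span <- c(con$tag_start, con$tag_end)
  rec_spans <- list(c(1, con$junction_n), c(con$junction_c, con$length))
  hits <- interdomain_clashes(model, tag_span, rec_spans, cutoff = 3.0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$distance, 2.5, tolerance = 2e-3)
  expect_equal(hits$tag_atom, "CB")
  # below the planted distance no contact remains
  expect_equal(nrow(interdomain_clashes(model, tag_span, rec_spans, 2.0)), 0)
  # monotone in cutoff
  counts <- sapply(c(4, 3, 2.6, 2), function(cut) {
    nrow(interdomain_clashes(model, tag_span, rec_spans, cut))
  })
  expect_true(all(diff(counts) <= 0))
  # pairs closer than 3 residues in sequence are excluded
  near <- interdomain_clashes(model, c(con$junction_n + 1, con$tag_end),
                              list(c(1, con$junction_n)), cutoff = 4.5)
  expect_true(all(abs(near$tag_resno - near$receptor_resno) >= 3))
  expect_error(interdomain_clashes(model, c(10, 50), list(c(40, 60))),
               class = "hf_data_error")
})

test_that("assessment ranks continuity, clashes, confidence and rmsd in order", {
  con <- make_construct()
  # reference shares the continuous model's chimera coordinates; map by
  # identity since it is numbered like the model, not like the receptor
  ref <- fusion_model_fixture(con)
  idmap <- tibble::tibble(model_resno = seq_len(con$length),
                          ref_resno = seq_len(con$length))
  models <- list(
    best = fusion_model_fixture(con),
    clashy = fusion_model_fixture(con, planted_clash = 2.4),
    lowconf = fusion_model_fixture(con, confidence = 60),
    broken = fusion_model_fixture(con, junction_helical = c(FALSE, TRUE)))
  reports <- lapply(names(models), function(nm) {
    con_i <- con
    con_i$name <- nm
    assess_model(models[[nm]], con_i, reference = ref, mapping = idmap)
  })
  ranked <- rank_assessments(dplyr::bind_rows(reports))
  # continuity first, then clash count, then confidence:
  # best (0 clash, conf 90) > lowconf (0 clash, conf 60) > clashy (1 clash)
  # > broken (discontinuous junction)
  expect_equal(ranked$name, c("best", "lowconf", "clashy", "broken"))
  expect_equal(ranked$rmsd_to_reference[ranked$name == "best"], 0,
               tolerance = 1e-6)
  # ties fall back to the stable name order
  tie <- dplyr::bind_rows(reports[[1]], reports[[1]])
  tie$name <- c("b_second", "a_first")
  expect_equal(rank_assessments(tie)$name, c("a_first", "b_second"))
  expect_s3_class(tidy(dplyr::bind_rows(reports)), "tbl_df")
  expect_s3_class(autoplot(dplyr::bind_rows(reports)), "ggplot")
})

test_that("reference mapping by author-number identity respects offsets", {
  con <- make_construct()
  model <- fusion_model_fixture(con)
  ref <- model
  map <- residue_mapping(model, ref)
  expect_equal(map$model_resno, map$ref_resno)
  expect_equal(nrow(map), con$length)
  shifted <- tibble::as_tibble(model)
  shifted$resno <- shifted$resno + 100L
  ref2 <- helixfuse:::new_structure_model(shifted, entry_id = "SHIFT")
  map2 <- residue_mapping(model, ref2, offset = 100L)
  expect_equal(nrow(map2), con$length)
  expect_equal(superpose_to_reference(model, ref2, map2)$rmsd, 0,
               tolerance = 1e-9)
  expect_error(residue_mapping(model, ref2, spans = list(c(1, 10))),
               class = "hf_data_error")
})
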