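fx_ref <- make_kinase_fixture()

test_that("activation-loop pLDDT is the min/mean of the CA B-factors", {
  fx <- make_kinase_fixture(default_fixture_spec(plddt = 90))
  pl <- min_plddt_activation_loop(fx$chain, fx$annotation)
  expect_equal(unname(pl), c(90, 90))
  # one weak residue dominates the minimum
  prof <- rep(90, 90)
  prof[45] <- 42.5  # inside the loop span (1-based residue 45)
  fx2 <- make_kinase_fixture(default_fixture_spec(plddt = prof))
  expect_equal(min_plddt_activation_loop(fx2$chain,
                                         fx2$annotation)[["min"]], 42.5)
  # direct arithmetic on a three-value loop profile
  prof3 <- rep(90, 90)
  loop_res <- activation_loop_ordinals(fx$annotation) + 1L
  prof3[loop_res] <- rep(c(60, 70, 80), length.out = length(loop_res))
  fx3 <- make_kinase_fixture(default_fixture_spec(plddt = prof3))
  pl3 <- min_plddt_activation_loop(fx3$chain, fx3$annotation)
  expect_equal(pl3[["min"]], 60)
  expect_equal(pl3[["mean"]],
               mean(rep(c(60, 70, 80), length.out = length(loop_res))))
})

test_that("experimental chains are refused for pLDDT operations", {
  s <- fx_ref$structure
  s$is_model <- FALSE
  expect_error(min_plddt_activation_loop(select_chain(s, "A"),
                                         fx_ref$annotation),
               "not flagged as a model")
})

test_that("model ranking is by min pLDDT with the documented tie-breaks", {
  sc <- data.frame(
    model_id = c("m1", "m2", "m3"),
    min_plddt_al = c(84.2, 50.1, 77.0),
    mean_plddt_al = c(90, 60, 80),
    active = c("true", "true", "true"),
    stringsAsFactors = FALSE
  )
  expect_equal(rank_models(sc)$min_plddt_al, c(84.2, 77.0, 50.1))
  # tie on min: higher mean first
  sc2 <- data.frame(model_id = c("a", "b"), min_plddt_al = c(70, 70),
                    mean_plddt_al = c(70, 80), stringsAsFactors = FALSE)
  expect_equal(rank_models(sc2)$model_id, c("b", "a"))
  # full tie: model id order (a total order regardless of input permutation)
  sc3 <- data.frame(model_id = c("z", "a"), min_plddt_al = c(70, 70),
                    mean_plddt_al = c(70, 70), stringsAsFactors = FALSE)
  expect_equal(rank_models(sc3)$model_id, c("a", "z"))
  expect_equal(rank_models(sc3[2:1, ])$model_id, c("a", "z"))
})

test_that("require_active drops inactive top scorers", {
  sc <- data.frame(
    model_id = c("good_low", "inactive_high"),
    min_plddt_al = c(70, 95), mean_plddt_al = c(70, 95),
    active = c("true", "false"), stringsAsFactors = FALSE
  )
  r <- rank_models(sc, require_active = TRUE)
  expect_equal(r$model_id, "good_low")
  sc$active <- c("false", "false")
  expect_warning(r2 <- rank_models(sc, require_active = TRUE), "no models")
  expect_equal(nrow(r2), 0)
})

test_that("identical sequences give an identity correspondence", {
  map <- build_correspondence(fx_ref$chain, fx_ref$chain,
                              fx_ref$annotation, fx_ref$annotation)
  expect_equal(map$identity, 1.0)
  expect_equal(map$ctd$model_ord, map$ctd$ref_ord)
  expect_equal(map$loop$model_ord, map$loop$ref_ord)
  # loop pairs cover the activation loop; CTD excludes it entirely
  expect_setequal(map$loop$model_ord,
                  activation_loop_ordinals(fx_ref$annotation))
  expect_length(intersect(map$ctd$model_ord, map$loop$model_ord), 0)
})

test_that("incomplete loop residues are dropped from the loop pair set", {
  s2 <- fx_ref$structure
  drop_res <- fx_ref$chain$residues$resno[
    fx_ref$chain$residues$ordinal %in% (fx_ref$annotation$dfg_d + 7:8)]
  s2$atoms <- s2$atoms[!(s2$atoms$resno %in% drop_res &
                           s2$atoms$elety == "O"), ]
  ch2 <- select_chain(s2, "A")
  map <- build_correspondence(fx_ref$chain, ch2, fx_ref$annotation,
                              fx_ref$annotation)
  expect_equal(nrow(map$loop),
               length(activation_loop_ordinals(fx_ref$annotation)) - 2L)
})

test_that("an N-terminal extension is absorbed by the alignment", {
  base <- default_fixture_spec()
  ext <- make_kinase_fixture(default_fixture_spec(
    sequence = paste0("GGG", base$sequence), anchors = base$anchors + 3L))
  map <- build_correspondence(ext$chain, fx_ref$chain, ext$annotation,
                              fx_ref$annotation)
  expect_equal(map$ctd$model_ord, map$ctd$ref_ord + 3L)
  r <- activation_loop_rmsd(ext$chain, fx_ref$chain, map)
  expect_equal(r$rmsd_al, 0, tolerance = 1e-9)
})

test_that("dissimilar sequences are rejected with advice", {
  other <- make_kinase_fixture(default_fixture_spec(
    sequence = paste0(
      "TTTTT", "AVK", "TTTT", "EAAAL", "TT", "HPN", "AAAL", "TTTT",
      "V", "HRD", "TTTTT", "A", "DFG", "TAT", "GTSGSGT", "G", "TSGSG",
      "APE", paste(rep("TT", 14), collapse = ""))))
  expect_error(build_correspondence(other$chain, fx_ref$chain,
                                    other$annotation, fx_ref$annotation),
               "identity")
})

test_that("a model equal to its reference scores zero RMSD", {
  map <- build_correspondence(fx_ref$chain, fx_ref$chain,
                              fx_ref$annotation, fx_ref$annotation)
  r <- activation_loop_rmsd(fx_ref$chain, fx_ref$chain, map)
  expect_equal(r$rmsd_al, 0, tolerance = 1e-9)
  expect_equal(r$rmsd_ctd, 0, tolerance = 1e-9)
  expect_equal(r$n_al_residues,
               length(activation_loop_ordinals(fx_ref$annotation)))
})

test_that("a pure loop translation appears undiluted in the loop RMSD", {
  s2 <- fx_ref$structure
  loop_resnos <- fx_ref$chain$residues$resno[
    fx_ref$chain$residues$ordinal %in%
      activation_loop_ordinals(fx_ref$annotation)]
  sel <- s2$atoms$resno %in% loop_resnos
  s2$atoms$x[sel] <- s2$atoms$x[sel] + 2.0
  ch2 <- select_chain(s2, "A")
  map <- build_correspondence(ch2, fx_ref$chain, fx_ref$annotation,
                              fx_ref$annotation)
  r <- activation_loop_rmsd(ch2, fx_ref$chain, map)
  expect_equal(r$rmsd_al, 2.0, tolerance = 1e-9)
  expect_equal(r$rmsd_ctd, 0, tolerance = 1e-9)
})

test_that("the two-stage RMSD equals an independent fit-then-measure oracle", {
  set.seed(31)
  for (i in 1:5) {
    m <- perturb_loop(fx_ref$structure, fx_ref$annotation, runif(1, 0.2, 2),
                      sample.int(1e6, 1))
    chm <- select_chain(m, "A")
    map <- build_correspondence(chm, fx_ref$chain, fx_ref$annotation,
                                fx_ref$annotation)
    r <- activation_loop_rmsd(chm, fx_ref$chain, map)
    expect_equal(r$rmsd_al, bio3d_two_stage_rmsd(chm, fx_ref$chain, map),
                 tolerance = 1e-9)
  }
})

test_that("loop RMSD is invariant to rigid transforms of the model", {
  m <- perturb_loop(fx_ref$structure, fx_ref$annotation, 1.0, 5)
  chm <- select_chain(m, "A")
  map <- build_correspondence(chm, fx_ref$chain, fx_ref$annotation,
                              fx_ref$annotation)
  r0 <- activation_loop_rmsd(chm, fx_ref$chain, map)$rmsd_al
  set.seed(17)
  for (i in 1:10) {
    m2 <- transform_structure(m, random_rigid_transform())
    ch2 <- select_chain(m2, "A")
    r <- activation_loop_rmsd(ch2, fx_ref$chain, map)$rmsd_al
    expect_equal(r, r0, tolerance = 1e-9)
  }
})

test_that("removing the worst loop pair never increases the loop RMSD", {
  m <- perturb_loop(fx_ref$structure, fx_ref$annotation, 1.5, 23)
  chm <- select_chain(m, "A")
  map <- build_correspondence(chm, fx_ref$chain, fx_ref$annotation,
                              fx_ref$annotation)
  full <- activation_loop_rmsd(chm, fx_ref$chain, map)$rmsd_al
  per <- vapply(seq_len(nrow(map$loop)), function(i) {
    m2 <- map
    m2$loop <- map$loop[-i, , drop = FALSE]
    activation_loop_rmsd(chm, fx_ref$chain, m2)$rmsd_al
  }, numeric(1))
  expect_lte(min(per), full + 1e-12)
})

test_that("benchmark fractions and histograms summarise best-model RMSDs", {
  s <- benchmark_summary(c(0.5, 1.5, 2.5))
  expect_equal(unname(s$fractions), c(1 / 3, 2 / 3))
  s0 <- benchmark_summary(rep(0, 4))
  expect_equal(unname(s0$fractions), c(1, 1))
  # a constructed 130-kinase distribution with 104 below 1 A
  set.seed(8)
  r <- c(runif(104, 0.1, 0.95), runif(13, 1.05, 1.95), runif(13, 2.05, 4))
  s1 <- benchmark_summary(r)
  expect_equal(unname(s1$counts), c(104, 117))
  expect_equal(unname(s1$fractions), c(104, 117) / 130, tolerance = 1e-12)
  expect_equal(sum(s1$histogram$count), 130)
})
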