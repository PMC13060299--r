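test_that("generator specs validate their invariants", {
  voc <- marker_vocabulary(c("A", "B"))
  p1 <- population_spec("p1", 0.6, c(0.2, 0.8))
  p2 <- population_spec("p2", 0.4, c(0.7, 0.1))
  expect_error(generator_spec(voc, list(p1), list("A"),
                              n_samples_per_class = c(x = 2L)),
               class = "cytoformer_validation_error")  # freqs don't sum to 1
  expect_error(generator_spec(voc, list(p1, p2), list(character(0)),
                              n_samples_per_class = c(x = 2L)),
               class = "cytoformer_validation_error")  # empty panel
  expect_error(population_spec("p", 0.5, c(0.1), marker_sds = -1),
               class = "cytoformer_parameter_error")
  spec <- generator_spec(voc, list(p1, p2), list(c("A", "B")),
                         n_samples_per_class = c(x = 2L, y = 2L),
                         effect = list(population = "p2",
                                       frequency_shift = 0.9))
  expect_error(generate_corpus(spec),
               class = "cytoformer_validation_error")  # zero mass
})

test_that("corpora are deterministic given the spec seed", {
  spec <- default_generator_spec(n_samples_per_class = c(a = 3L, b = 3L),
                                 cells_per_sample = c(50L, 80L), seed = 31)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$samples, `[[`, "events"),
                   lapply(c2$samples, `[[`, "events"))
})

test_that("planted frequency shift appears at its configured magnitude", {
  shift <- 0.10
  spec <- default_generator_spec(n_samples_per_class = c(control = 12L,
                                                         case = 12L),
                                 cells_per_sample = c(2000L, 2000L),
                                 frequency_shift = shift, seed = 5)
  corpus <- generate_corpus(spec)
  truth <- corpus$truth
  nk_frac <- truth$NK / rowSums(truth[, c("T_helper", "T_cytotoxic",
                                          "B_cell", "NK", "Myeloid")])
  diff <- mean(nk_frac[truth$class == "case"]) -
    mean(nk_frac[truth$class == "control"])
  # binomial + between-sample error at n = 2000 cells x 12 samples
  se <- sqrt(0.2 * 0.8 / 2000 / 12) * sqrt(2)
  expect_lt(abs(diff - shift), 3 * se + 0.01)
})

test_that("a null effect leaves class-conditional distributions exchangeable", {
  spec <- default_generator_spec(n_samples_per_class = c(control = 10L,
                                                         case = 10L),
                                 frequency_shift = 0, seed = 8,
                                 cells_per_sample = c(400L, 400L))
  corpus <- generate_corpus(spec)
  truth <- corpus$truth
  nk <- truth$NK / 400
  p <- t.test(nk[truth$class == "case"], nk[truth$class == "control"])$p.value
  expect_gt(p, 0.01)
})

test_that("mixture marginals converge to the frequency-weighted population means", {
  spec <- default_generator_spec(n_samples_per_class = c(control = 1L,
                                                         case = 0L),
                                 cells_per_sample = c(20000L, 20000L),
                                 seed = 3)
  spec$panels <- list(spec$vocabulary$markers)  # full panel, no batch mixing
  spec$panel_probs <- 1
  spec$batch_additive_sd <- 1e-12; spec$batch_scale_sd <- 1e-12
  corpus <- generate_corpus(spec)
  s <- corpus$samples[[1]]
  freqs <- vapply(spec$populations, function(p) p$frequency, numeric(1))
  mns <- sapply(seq_along(spec$vocabulary$markers), function(j)
    sum(freqs * vapply(spec$populations, function(p) p$marker_means[j],
                       numeric(1))))
  emp <- colMeans(s$events)
  # mixture sd per marker is < 0.35 on this design; 3 standard errors
  expect_true(all(abs(emp - mns) < 3 * 0.35 / sqrt(20000) + 0.01))
})

test_that("worked example corpus is stable, panel-diverse and store-compatible", {
  c1 <- worked_example_corpus()
  c2 <- worked_example_corpus()
  expect_identical(c1$truth, c2$truth)
  expect_length(c1$samples, 40)
  expect_gte(length(unique(c1$truth$panel)), 2)
  ncells <- vapply(c1$samples, function(s) nrow(s$events), numeric(1))
  expect_true(all(ncells >= 500 & ncells <= 1000))
  # samples round-trip through the plain-matrix store path
  dir <- tempfile()
  write_sample_store(c1$samples[1:2], dir)
  back <- read_sample_store(dir)
  expect_equal(back[[1]]$events, c1$samples[[1]]$events)
  # per-cell ground truth is aligned with rows
  pops <- attr(c1$samples[[1]], "cell_populations")
  expect_length(pops, nrow(c1$samples[[1]]$events))
})
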