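test_that("the generator is deterministic under a fixed seed", {
  cfg <- survey_config(n_plots = 20, n_otus = 40, seed = 9)
  a <- simulate_survey(cfg)
  b <- simulate_survey(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth_otus, b$truth_otus)
  c <- simulate_survey(survey_config(n_plots = 20, n_otus = 40, seed = 10))
  expect_false(identical(a$counts, c$counts))
})

test_that("environment tables respect configured bounds and correlations", {
  cfg <- survey_config(n_plots = 5, pH_range = c(4, 7), seed = 2)
  meta <- generate_environment(cfg)
  expect_equal(nrow(meta), 5)
  expect_true(all(meta$pH_KCl >= 4 & meta$pH_KCl <= 7))
  big <- generate_environment(survey_config(n_plots = 500,
                                            pH_range = c(3, 8), seed = 4))
  expect_gte(cor(big$pH_KCl, big$Ca, method = "spearman"), 0.4)
  expect_lt(cor(big$pH_KCl, big$ln_CN, method = "spearman"), 0)
  # tree shares form a (sub-)simplex; EcM % is their EcM-genus sum
  tree_cols <- paste0(c("Picea", "Pinus", "Betula", "Quercus", "Salix",
                        "Alnus", "Corylus", "Tilia", "Acer", "Fraxinus"),
                      "_pct")
  shares <- as.matrix(big[tree_cols])
  expect_true(all(shares >= 0 & shares <= 100))
  expect_true(all(rowSums(shares) <= 100.5))
  expect_true(all(big$ecm_plant_pct <= rowSums(shares) + 1e-9))
})

test_that("counts conserve drawn depths and honour the clamp", {
  cfg <- survey_config(n_plots = 30, n_otus = 50, frac_spoiled = 0,
                       frac_low_depth = 0, n_control_samples = 0, seed = 6)
  sv <- simulate_survey(cfg)
  tot <- rowSums(otu_matrix(sv$counts))
  expect_true(all(tot >= cfg$min_depth_truth))
  expect_true(all(tot <= cfg$max_depth_truth))
})

test_that("host-linked OTUs are absent where their host is absent", {
  cfg <- survey_config(n_plots = 60, n_otus = 80, frac_spoiled = 0,
                       frac_low_depth = 0, n_control_samples = 0, seed = 8)
  sv <- simulate_survey(cfg)
  m <- otu_matrix(sv$counts)
  linked <- dplyr::filter(sv$truth_otus, !is.na(host_taxon))
  expect_gt(nrow(linked), 0)
  for (i in seq_len(nrow(linked))) {
    host_pct <- sv$metadata[[paste0(linked$host_taxon[i], "_pct")]]
    absent <- host_pct == 0
    if (any(absent)) {
      expect_true(all(m[absent, linked$otu_id[i]] == 0))
    }
  }
})

test_that("injected artifacts carry their truth flags", {
  cfg <- survey_config(n_plots = 100, frac_spoiled = 0.1,
                       frac_low_depth = 0.05, seed = 13)
  sv <- simulate_survey(cfg)
  m <- otu_matrix(sv$counts)
  tr <- sv$truth_samples
  # spoiled samples: max mold-OTU share above the group threshold
  lim <- c(Mortierellales = 0.15, Umbelopsidales = 0.15,
           Pezizomycotina_mold = 0.30)
  sp <- dplyr::filter(tr, spoiled_flag, !low_depth_flag)
  expect_equal(nrow(sp), 10)
  grp_of <- setNames(sv$taxonomy$mold_group, sv$taxonomy$otu_id)
  for (i in seq_len(nrow(sp))) {
    g <- sp$spoiling_mold_group[i]
    otus <- names(grp_of)[!is.na(grp_of) & grp_of == g]
    share <- max(m[sp$sample_id[i], otus]) / sum(m[sp$sample_id[i], ])
    expect_gt(share, lim[[g]])
  }
  # low-depth samples fall below the depth filter
  low <- tr$sample_id[tr$low_depth_flag]
  expect_equal(length(low), 5)
  expect_true(all(rowSums(m[low, , drop = FALSE]) < 500))
  # controls: negatives near-empty, positives a fixed mock community
  ctl <- tr$sample_id[tr$control_flag]
  expect_equal(length(ctl), cfg$n_control_samples)
  neg <- grep("neg", ctl, value = TRUE)
  expect_true(all(rowSums(m[neg, , drop = FALSE]) <= 50))
  pos <- grep("pos", ctl, value = TRUE)
  expect_true(all(rowSums(m[pos, , drop = FALSE] > 0) <= 8))
})

test_that("frac_spoiled = 0 leaves non-control plot counts untouched", {
  cfg <- survey_config(n_plots = 25, n_otus = 40, frac_spoiled = 0,
                       frac_low_depth = 0, n_control_samples = 4, seed = 3)
  meta <- generate_environment(cfg)
  tab <- generate_otu_table(meta, cfg)
  before <- tab$counts
  after <- inject_artifacts(tab, meta, cfg)
  plot_ids <- meta$sample_id
  expect_equal(dplyr::filter(after$counts, sample_id %in% plot_ids),
               before)
})

test_that("invalid configurations are rejected", {
  expect_error(survey_config(n_plots = 1), "n_plots")
  expect_error(survey_config(pH_range = c(1, 8)), "pH_range")
  expect_error(survey_config(pH_range = c(8, 3)), "pH_range")
  expect_error(survey_config(frac_spoiled = 0.7, frac_low_depth = 0.5),
               "exceed 1")
  expect_error(survey_config(niche_width_range = c(0, 1)), "positive")
})

test_that("pH optima of well-sampled OTUs are recoverable from counts", {
  # the generator's central recoverability property: for the most
  # sequenced free-living OTU with an optimum well inside the gradient,
  # a quadratic fit to the log-ratio abundance (where present) finds the
  # optimum within 0.3 pH units in >= 90% of seeds
  errs <- vapply(1:10, function(s) {
    cfg <- survey_config(n_plots = 300, frac_spoiled = 0,
                         frac_low_depth = 0, n_control_samples = 0,
                         seed = 100 + s)
    sv <- simulate_survey(cfg)
    m <- otu_matrix(sv$counts)
    tr <- sv$truth_otus
    ids <- tr$otu_id[is.na(tr$host_taxon) &
                       tr$niche_optimum > cfg$pH_range[1] + 1.5 &
                       tr$niche_optimum < cfg$pH_range[2] - 1.5]
    cand <- ids[which.max(colSums(m[, ids]))]
    keep <- m[, cand] > 0
    y <- logratio_pct(100 * m[, cand] / rowSums(m))
    fit <- fit_quadratic_model(
      data.frame(y = y[keep], pH = sv$metadata$pH_KCl[keep]), "y", "pH")
    abs(fit$terms$vertex - tr$niche_optimum[tr$otu_id == cand])
  }, numeric(1))
  expect_gte(mean(errs <= 0.3), 0.9)
})
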