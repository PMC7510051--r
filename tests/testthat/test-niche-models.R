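test_that("a single candidate is selected without competition", {
  df <- data.frame(y = rnorm(50), x = rnorm(50))
  sel <- select_predictors(df, "y", "x")
  expect_equal(sel$predictor, "x")
  expect_true(sel$selected)
})

test_that("a real gradient outranks noise candidates and decoys", {
  set.seed(31)
  pH <- runif(300, 3, 8)
  y <- 100 * exp(-(pH - 5.8)^2 / 2) + rnorm(300, 0, 8)
  noise <- as.data.frame(matrix(rnorm(300 * 9), 300))
  names(noise) <- paste0("n", 1:9)
  df <- cbind(data.frame(y = y, pH = pH), noise)
  sel <- select_predictors(df, "y", c("pH", names(noise)), seed = 2)
  expect_equal(sel$predictor[1], "pH")
  expect_true(sel$selected[sel$predictor == "pH"])
  expect_lte(sum(sel$selected), 2)
})

test_that("pure-noise responses rarely select anything", {
  n_sel <- vapply(1:3, function(s) {
    set.seed(600 + s)
    df <- as.data.frame(matrix(rnorm(150 * 9), 150))
    names(df) <- c("y", paste0("p", 1:8))
    sum(select_predictors(df, "y", paste0("p", 1:8), seed = s)$selected)
  }, numeric(1))
  expect_gte(sum(n_sel == 0), 2)
  expect_lte(sum(n_sel), 2)
})

test_that("rows with missing values are dropped with a message", {
  df <- data.frame(y = rnorm(60), a = rnorm(60), b = rnorm(60))
  df$a[1:5] <- NA
  expect_message(sel <- select_predictors(df, "y", c("a", "b"), seed = 1),
                 "Dropped 5")
  expect_equal(attr(sel, "n"), 55)
})

test_that("noiseless quadratic responses are recovered exactly", {
  set.seed(5)
  x_raw <- runif(200, 2, 9)
  xs <- as.numeric(scale(x_raw))
  y <- 2 + 3 * xs - xs^2
  # noiseless data: lm warns about the perfect fit, which is the point
  fit <- suppressWarnings(
    fit_quadratic_model(data.frame(y = y, x = x_raw), "y", "x"))
  expect_equal(fit$terms$b0, 2, tolerance = 1e-8)
  expect_equal(fit$terms$b1, 3, tolerance = 1e-8)
  expect_equal(fit$terms$b2, -1, tolerance = 1e-8)
  expect_equal(fit$terms$r2, 100, tolerance = 1e-8)
  expect_equal(fit$combined_r2, 100, tolerance = 1e-8)
  # vertex mapped back to the raw predictor scale
  expect_equal(fit$terms$vertex, 1.5 * sd(x_raw) + mean(x_raw))
})

test_that("constant responses give null fits, not NaN", {
  fit <- fit_quadratic_model(data.frame(y = rep(3, 40), x = rnorm(40)),
                             "y", "x")
  expect_equal(fit$terms$b1, 0)
  expect_equal(fit$terms$b2, 0)
  expect_equal(fit$terms$r2, 0)
  expect_equal(fit$terms$shape, "flat")
  expect_equal(fit$combined_r2, 0)
})

test_that("combined R2 is at least the best single-predictor R2", {
  set.seed(17)
  df <- data.frame(a = rnorm(120), b = rnorm(120))
  df$y <- df$a - 0.5 * df$a^2 + 0.3 * df$b + rnorm(120, 0, 0.5)
  fit <- fit_quadratic_model(df, "y", c("a", "b"))
  expect_gte(fit$combined_r2, max(fit$terms$r2) - 1e-9)
})

test_that("shape classification follows the directionality rules", {
  # significant negative curvature, vertex mid-range: unimodal
  expect_equal(classify_shape(0, -1, 0.5, 0.001, -1.6, 1.6), "unimodal")
  # no curvature, significant positive slope
  expect_equal(classify_shape(2, 0, 0.001, 0.8, -1.6, 1.6), "positive")
  expect_equal(classify_shape(-2, 0, 0.001, 0.8, -1.6, 1.6), "negative")
  # nothing significant: flat
  expect_equal(classify_shape(0.1, 0.1, 0.6, 0.6, -1.6, 1.6), "flat")
  # concave with vertex beyond the 95th percentile: rise-then-plateau
  expect_equal(classify_shape(4, -1, 0.001, 0.001, -1.6, 1.6),
               "saturating")
  # concave with vertex below the 5th percentile: decline
  expect_equal(classify_shape(-4, -1, 0.001, 0.001, -1.6, 1.6), "negative")
  # convex with interior vertex: U
  expect_equal(classify_shape(0, 1, 0.5, 0.001, -1.6, 1.6), "U")
  expect_equal(classify_shape(4, 1, 0.001, 0.001, -1.6, 1.6), "positive")
})

test_that("fitted shapes match the generating response", {
  set.seed(23)
  x <- runif(300, 3, 8)
  uni <- -(x - 5.5)^2 + rnorm(300, 0, 0.5)
  fit <- fit_quadratic_model(data.frame(y = uni, x = x), "y", "x")
  expect_equal(fit$terms$shape, "unimodal")
  expect_equal(fit$terms$vertex, 5.5, tolerance = 0.1)
  pos <- 2 * x + rnorm(300)
  expect_equal(
    fit_quadratic_model(data.frame(y = pos, x = x), "y", "x")$terms$shape,
    "positive")
})

test_that("tidy and glance expose the niche-model results", {
  set.seed(2)
  df <- data.frame(y = rnorm(60), x = rnorm(60))
  df$y <- df$y + df$x
  fit <- fit_quadratic_model(df, "y", "x")
  td <- tidy(fit)
  expect_true(all(c("response", "predictor", "b0", "b1", "b2", "r2",
                    "shape") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 60)
  expect_equal(gl$n_predictors, 1)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("per-OTU niche models honour prevalence and find host links", {
  cfg <- survey_config(n_plots = 200, frac_spoiled = 0, frac_low_depth = 0,
                       n_control_samples = 0, seed = 41)
  sv <- simulate_survey(cfg)
  m <- otu_matrix(sv$counts)
  rare <- names(which(colSums(m > 0) < 5))[1]
  expect_message(
    expect_null(otu_niche_model(sv$counts, sv$metadata, rare,
                                c("pH_KCl", "Ca"))),
    "skipped")
  expect_error(otu_niche_model(sv$counts, sv$metadata, "nope", "pH_KCl"),
               "Unknown OTU")
  # a Picea-linked OTU should put the host share among selected predictors
  linked <- dplyr::filter(sv$truth_otus, host_taxon == "Picea")
  prev <- colSums(m[, linked$otu_id, drop = FALSE] > 0)
  cand <- linked$otu_id[which.max(prev)]
  fit <- otu_niche_model(sv$counts, sv$metadata, cand,
                         c("pH_KCl", "Picea_pct", "Betula_pct", "Ca",
                           "d15N"),
                         seed = 3)
  expect_true("Picea_pct" %in% fit$terms$predictor)
})
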