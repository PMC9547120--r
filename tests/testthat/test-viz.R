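test_that("wide-to-long reshape is lossless", {
  d <- sim_worked_example(n = 40, seed = 6)
  long <- wide_to_long(d, list(x = paste0("x", 1:5), y = paste0("y", 1:5)))
  expect_equal(nrow(long), 40 * 5 * 2)
  # pivot back and compare cell by cell
  for (v in c("x3", "y5")) {
    sub <- long[long$variable == v, ]
    sub <- sub[order(sub$id), ]
    expect_equal(sub$value, d[[v]])
  }
})

test_that("a 20% sample of 500 individuals draws exactly 100", {
  d <- sim_worked_example(n = 500, seed = 8)
  p <- plot_trajectories(d, paste0("x", 1:5), random_sample_frac = .2,
                         seed = 99)
  expect_s3_class(p, "ggplot")
  expect_equal(length(unique(p$data$id)), 100)
  p2 <- plot_trajectories(d, paste0("x", 1:5), random_sample_frac = .2,
                          seed = 99)
  expect_setequal(unique(p$data$id), unique(p2$data$id))
})

test_that("full-sample long data drops exactly the missing cells", {
  d <- sim_worked_example(n = 200, seed = 12)
  p <- plot_trajectories(d, paste0("x", 1:5))
  n_missing <- sum(is.na(d[, paste0("x", 1:5)]))
  expect_equal(nrow(p$data), 200 * 5 - n_missing)
})

test_that("missing occasions break lines unless connect_missing is set", {
  d <- tibble::tibble(id = 1:2, x1 = c(1, 2), x2 = c(NA, 2.5),
                      x3 = c(3, 3.5))
  p <- plot_trajectories(d, paste0("x", 1:3))
  # id 1 splits into two one-point segments around the missing x2
  series_id1 <- unique(p$data$series[p$data$id == 1])
  expect_equal(length(series_id1), 2)
  pc <- plot_trajectories(d, paste0("x", 1:3), connect_missing = TRUE)
  expect_equal(length(unique(pc$data$series[pc$data$id == 1])), 1)
})

test_that("diagram layout mirrors the compiled structural pattern", {
  m <- compile_lcsm(as_uni_spec(worked_model()), 5)
  lay <- diagram_layout(m)
  expect_equal(sum(lay$edges$label == "beta_x"), 4)
  expect_equal(sum(lay$edges$label == "phi_x"), 3)
  g2_loadings <- lay$edges[lay$edges$from == "g2" & lay$edges$kind ==
                             "directed", ]
  expect_equal(nrow(g2_loadings), 4)
  expect_true(all(g2_loadings$label == "1"))
  # edge set = nonzero pattern of A plus free off-diagonal pattern of S
  n_A <- sum(m$A != 0 | m$A_lab != "")
  Su <- m$S_lab; Su[lower.tri(Su, diag = TRUE)] <- ""
  n_S <- sum(Su != "")
  expect_equal(nrow(lay$edges), n_A + n_S)
  expect_true(all(lay$nodes$shape[lay$nodes$layer == "observed"] == "square"))
  expect_true(all(lay$nodes$shape[lay$nodes$layer != "observed"] == "circle"))
})

test_that("lagged coupling shows as diagonal edges between change layers", {
  m <- compile_lcsm(bi_spec(worked_model(), worked_model(),
                            list(xi_lag_yx = TRUE)), 5)
  lay <- diagram_layout(m)
  coup <- lay$edges[lay$edges$label == "xi_lag_yx", ]
  expect_setequal(paste(coup$from, coup$to),
                  c("dx2 dy3", "dx3 dy4", "dx4 dy5"))
})

test_that("residual nodes appear only on request, one per observed score", {
  m <- compile_lcsm(as_uni_spec(worked_model()), 5)
  lay0 <- diagram_layout(m)
  expect_equal(sum(lay0$nodes$layer == "residual"), 0)
  lay1 <- diagram_layout(m, show_residuals = TRUE)
  expect_equal(sum(lay1$nodes$layer == "residual"), 5)
  expect_equal(nrow(lay1$edges), nrow(lay0$edges) + 5)
})

test_that("plot_lcsm renders and attaches its layout", {
  m <- compile_lcsm(bi_spec(worked_model(), worked_model(),
                            list(xi_lag_yx = TRUE)), 5)
  p <- plot_lcsm(m)
  expect_s3_class(p, "ggplot")
  lay <- attr(p, "layout")
  expect_s3_class(lay, "lcsm_layout")
  js <- tempfile(fileext = ".json")
  write_layout_json(lay, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(parsed$edges), nrow(lay$edges))
})
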