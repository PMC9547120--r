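test_that("constant-change layout has the expected fixed unit paths", {
  m <- compile_lcsm(uni_spec(alpha_constant = TRUE), 5)
  A <- m$A; L <- m$A_lab
  # fixed cells: value set, no label
  fixed <- which(A != 0 & L == "", arr.ind = TRUE)
  from <- m$vars[fixed[, 2]]; to <- m$vars[fixed[, 1]]
  expect_equal(sum(grepl("^lx", from) & grepl("^lx", to)), 4) # autoregressions
  expect_equal(sum(grepl("^dx", from) & grepl("^lx", to)), 4) # change defs
  expect_equal(sum(from == "g2"), 4)                          # factor loadings
  expect_equal(sum(grepl("^lx", from) & grepl("^x", to)), 5)  # measurement
  expect_true(all(A[A != 0 & L == ""] %in% 1))
  # no free cells in A for this spec; free cells only in S and m
  expect_true(all(L == ""))
  expect_true(any(m$S_lab != ""))
  expect_true(any(m$m_lab != ""))
})

test_that("equality constraints put one label on the right number of cells", {
  m <- compile_lcsm(as_uni_spec(worked_model()), 5)
  expect_equal(nrow(m$label_map$beta_x), 4)   # t = 2..5
  expect_equal(nrow(m$label_map$phi_x), 3)    # t = 3..5
  expect_equal(nrow(m$label_map$sigma2_ux), 5)
  expect_equal(nrow(m$label_map$gamma_lx1), 1)
  expect_setequal(names(m$label_map), m$param_table$label)
})

test_that("lagged change-to-change coupling lands on the diagonal cells", {
  spec <- bi_spec(worked_model(), worked_model(), list(xi_lag_yx = TRUE))
  m <- compile_lcsm(spec, 5)
  cells <- m$label_map$xi_lag_yx
  expect_equal(nrow(cells), 3)
  expect_setequal(paste(cells$row, cells$col),
                  c("dy3 dx2", "dy4 dx3", "dy5 dx4"))
})

test_that("concurrent and lagged coupling variants use the specified sources", {
  base <- list(alpha_constant = TRUE)
  m1 <- compile_lcsm(bi_spec(base, base, list(delta_con_yx = TRUE)), 5)
  expect_setequal(paste(m1$label_map$delta_con_yx$row,
                        m1$label_map$delta_con_yx$col),
                  c("dy2 lx2", "dy3 lx3", "dy4 lx4", "dy5 lx5"))
  m2 <- compile_lcsm(bi_spec(base, base, list(delta_lag_yx = TRUE)), 5)
  expect_setequal(paste(m2$label_map$delta_lag_yx$row,
                        m2$label_map$delta_lag_yx$col),
                  c("dy3 lx2", "dy4 lx3", "dy5 lx4"))
  m3 <- compile_lcsm(bi_spec(base, base, list(xi_con_xy = TRUE)), 5)
  expect_setequal(paste(m3$label_map$xi_con_xy$row,
                        m3$label_map$xi_con_xy$col),
                  c("dx2 dy2", "dx3 dy3", "dx4 dy4", "dx5 dy5"))
})

test_that("S pattern is symmetric and free cells carry exactly one label", {
  spec <- bi_spec(worked_model(), worked_model(), list(xi_lag_yx = TRUE))
  m <- compile_lcsm(spec, 5)
  expect_identical(m$S_lab, t(m$S_lab))
  expect_identical(m$S, t(m$S))
  # every labelled cell corresponds to an inventory label
  labs <- unique(c(m$A_lab[m$A_lab != ""], m$S_lab[m$S_lab != ""],
                   m$m_lab[m$m_lab != ""]))
  expect_setequal(labs, m$param_table$label)
})

test_that("piecewise change factors partition the change scores", {
  m <- compile_lcsm(uni_spec(alpha_piecewise = TRUE, alpha_piecewise_num = 3),
                    6)
  g2_targets <- m$vars[which(m$A[, "g2"] != 0)]
  g3_targets <- m$vars[which(m$A[, "g3"] != 0)]
  expect_setequal(g2_targets, c("dx2", "dx3"))
  expect_setequal(g3_targets, c("dx4", "dx5", "dx6"))
  expect_length(intersect(g2_targets, g3_targets), 0)
})

test_that("linear change factor has loadings t - 1", {
  m <- compile_lcsm(uni_spec(alpha_linear = TRUE), 5)
  loadings <- m$A[paste0("dx", 2:5), "g2"]
  expect_equal(unname(loadings), c(1, 2, 3, 4))
})

test_that("piecewise coupling splits each path label at the change point", {
  spec <- bi_spec(list(alpha_constant = TRUE), list(alpha_constant = TRUE),
                  list(xi_con_yx = TRUE, coupling_piecewise = TRUE,
                       coupling_piecewise_num = 3))
  m <- compile_lcsm(spec, 5)
  expect_setequal(paste(m$label_map$xi_con_yx_p1$row,
                        m$label_map$xi_con_yx_p1$col),
                  c("dy2 dx2", "dy3 dx3"))
  expect_setequal(paste(m$label_map$xi_con_yx_p2$row,
                        m$label_map$xi_con_yx_p2$col),
                  c("dy4 dx4", "dy5 dx5"))
})

test_that("duplicate variable names are rejected", {
  expect_error(compile_lcsm(bi_spec(worked_model(), worked_model(),
                                    list(xi_lag_yx = TRUE)), 5,
                            var_y = paste0("x", 1:5)),
               "distinct")
})
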