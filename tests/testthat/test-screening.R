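# two exactly orthogonal, mean-zero base vectors for constructed correlations
z1 <- c(1, 1, -1, -1, 1, 1, -1, -1)
z2 <- c(1, -1, 1, -1, 1, -1, 1, -1)

test_that("VIF is exact on constructed correlation structures", {
  X <- cbind(a = z1, b = z2) # sample correlation exactly 0
  expect_equal(unname(compute_vif(X)), c(1, 1), tolerance = 1e-12)
  # sample correlation exactly 0.9: VIF = 1/(1 - 0.81)
  X2 <- cbind(a = z1, b = 0.9 * z1 + sqrt(1 - 0.9^2) * z2)
  expect_equal(unname(compute_vif(X2)), rep(1 / 0.19, 2), tolerance = 1e-10)
  expect_equal(round(unname(compute_vif(X2))[1], 4), 5.2632)
  # perfect collinearity reports Inf, not an error
  X3 <- cbind(a = z1, b = 2 * z1, c = z2)
  expect_true(all(is.infinite(compute_vif(X3)[c("a", "b")])))
  expect_error(compute_vif(cbind(z1)), "two columns")
  expect_error(compute_vif(cbind(a = z1, b = rep(1, 8))), "constant")
})

test_that("VIF agrees with the correlation-matrix-inverse oracle", {
  set.seed(5)
  n <- 120
  X <- matrix(rnorm(n * 6), n, 6) %*% chol(0.5^abs(outer(1:6, 1:6, "-")))
  colnames(X) <- paste0("V", 1:6)
  vif <- compute_vif(X)
  oracle <- diag(solve(stats::cor(X)))
  expect_equal(unname(vif), unname(oracle), tolerance = 1e-8)
})

test_that("VIF is invariant to affine rescaling of columns", {
  set.seed(6)
  X <- matrix(rnorm(300), 100, 3)
  colnames(X) <- c("a", "b", "c")
  X2 <- X
  X2[, 2] <- 10 * X[, 2] - 7
  expect_equal(compute_vif(X), compute_vif(X2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the iterative filter eliminates exactly the collinear offender", {
  set.seed(9)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  X <- cbind(X1 = x1, X2 = x2, X3 = x1 + x2 + rnorm(n, 0, 0.05))
  first_vif <- compute_vif(X)
  out <- iterative_vif_filter(X, threshold = 5)
  kept <- out$retained$all
  expect_length(kept, 2L)
  # the algorithm must have dropped the initial worst offender
  dropped <- setdiff(colnames(X), kept)
  expect_equal(dropped, names(which.max(first_vif)))
  expect_true(all(compute_vif(X[, kept]) <= 5))
  # near-orthogonal columns all survive in a single round
  Xo <- cbind(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  out2 <- iterative_vif_filter(Xo, threshold = 5)
  expect_equal(out2$retained$all, c("A", "B", "C"))
  expect_equal(max(out2$vif_table$round), 1L)
  # infinite threshold is the identity filter
  out3 <- iterative_vif_filter(X, threshold = Inf)
  expect_equal(out3$retained$all, colnames(X))
})

test_that("blocks are filtered independently and singleton blocks survive", {
  set.seed(10)
  n <- 150
  a <- rnorm(n)
  X <- cbind(SE1 = a, SE2 = a + rnorm(n, 0, 0.01), EX1 = rnorm(n))
  out <- iterative_vif_filter(X, threshold = 5, block_labels = c("SE", "SE", "EX"))
  expect_length(out$retained$SE, 1L) # collinear pair reduced, survivor kept
  expect_equal(out$retained$EX, "EX1")
  expect_true(any(is.na(out$vif_table$vif[out$vif_table$block == "SE"])) ||
                all(table(out$vif_table$block) >= 1))
  # the logged table reproduces the eliminations
  dropped <- out$vif_table$covariate[out$vif_table$dropped]
  expect_equal(setdiff(c("SE1", "SE2"), out$retained$SE), dropped)
})

test_that("forest importance is deterministic and separates signal from noise", {
  set.seed(3)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("V", 1:4)))
  y <- 2 * X[, 1] + rnorm(n, 0, 0.5)
  i1 <- forest_importance(X, y, n_trees = 100, seed = 7)
  i2 <- forest_importance(X, y, n_trees = 100, seed = 7)
  expect_identical(i1, i2)
  expect_equal(sum(i1$mdi), 1, tolerance = 1e-12)
  expect_equal(names(which.max(i1$mdi)), "V1")
  expect_equal(names(which.max(i1$mda)), "V1")
  # noise features: MDA near zero relative to the signal feature
  expect_lt(max(i1$mda[2:4]), 0.1 * i1$mda[["V1"]])
  expect_error(forest_importance(X, rep(1, n), n_trees = 50), "constant")
  expect_error(forest_importance(X[1:10, ], y[1:10], n_trees = 50), "30 rows")
})

test_that("top-k intersection selection follows the documented tie-breaks", {
  mdi <- c(A = 4, B = 3, C = 2, D = 1)
  mda <- c(A = 4, C = 3, B = 2, D = 1)
  expect_equal(select_covariates(mdi, mda, 2), "A") # {A,B} n {A,C}
  mda2 <- c(A = 4, B = 3, C = 2, D = 1)
  expect_equal(select_covariates(mdi, mda2, 3), c("A", "B", "C"))
  expect_equal(select_covariates(mdi, mda2, 4), c("A", "B", "C", "D"))
  expect_error(select_covariates(mdi, mda, 5), "exceed")
  mda3 <- c(A = 1, B = 2, C = 3, D = 4)
  expect_warning(sel <- select_covariates(c(A = 4, B = 3, C = 2, D = 1), mda3, 2),
                 "disjoint")
  expect_length(sel, 0L)
})

test_that("the full screen runs at candidate scale with a complete audit trail", {
  sim <- generate_panel(sim_config(rows = 6, cols = 6, n_years = 8,
                                   n_se = 20, n_ex = 12, n_time_invariant = 4,
                                   rho = 0.75, seed = 17))
  panel <- preprocess_panel(sim$panel)
  res <- screen_covariates(panel, vif_threshold = 5, n_trees = 120, seed = 5)
  kept <- unlist(res$retained_after_vif, use.names = FALSE)
  # every selected covariate survived the VIF step
  expect_true(all(res$selected %in% kept))
  # survivors' final VIFs are at or below the threshold per block
  tab <- res$vif_table
  for (blk in c("SE", "EX")) {
    last <- tab[tab$block == blk & tab$round == max(tab$round[tab$block == blk]), ]
    expect_true(all(last$vif[!last$dropped] <= 5, na.rm = TRUE))
  }
  # every elimination is explained: dropped rows carry the round's max VIF
  for (r in unique(tab$round)) {
    for (blk in unique(tab$block)) {
      rows <- tab[tab$round == r & tab$block == blk, ]
      if (any(rows$dropped)) {
        expect_equal(rows$vif[rows$dropped], max(rows$vif), tolerance = 1e-12)
      }
    }
  }
  # importances are reported for exactly the VIF survivors
  expect_setequal(names(res$mdi), kept)
  expect_setequal(names(res$mda), kept)
  expect_equal(res$config$k, ceiling(length(kept) / 2))
})
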