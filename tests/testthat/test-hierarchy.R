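test_that("default topologies have the documented shape", {
  arch <- default_topology("archaea")
  expect_setequal(arch$leaves, c("CYT", "PM", "EXT"))
  expect_length(arch$internal, 2)

  bac <- default_topology("bacteria")
  expect_setequal(bac$leaves, c("CYT", "PM", "PERI", "OM", "EXT", "FIM"))
  expect_length(bac$internal, 5)

  euk <- default_topology("eukaryota")
  expect_length(euk$leaves, 18)
  expect_length(euk$internal, 17)
  # the root decision separates membrane from non-membrane classes
  kids <- euk$children[[euk$root]]
  sides <- lapply(kids, function(ch) leaves_under(euk, ch))
  mem <- c("CHLM", "ERM", "GOLM", "MITM", "NUCM", "PERM", "PM", "VACM")
  is_mem <- vapply(sides, function(s) all(s %in% mem), logical(1))
  expect_equal(sort(is_mem), c(FALSE, TRUE))
  expect_setequal(unlist(sides), euk$leaves)

  expect_error(default_topology("viruses"), "should be one of")
})

test_that("node dataset assembly groups leaf classes by child subtree", {
  arch <- default_topology("archaea")
  labeled <- tibble::tibble(
    id = sprintf("p%02d", 1:9),
    class = rep(c("EXT", "PM", "CYT"), each = 3))
  # at the root the non-cytosolic child gathers EXT and PM against CYT
  ds <- assemble_node_dataset(arch, arch$root, labeled)
  expect_setequal(ds$a_ids, labeled$id[labeled$class %in% c("EXT", "PM")])
  expect_setequal(ds$b_ids, labeled$id[labeled$class == "CYT"])

  bac <- default_topology("bacteria")
  lab2 <- tibble::tibble(id = sprintf("b%02d", 1:60),
                         class = rep(bac$leaves, each = 10))
  ds2 <- assemble_node_dataset(bac, bac$root, lab2)
  expect_equal(length(ds2$a_ids) + length(ds2$b_ids), 60)

  expect_error(assemble_node_dataset(arch, "CYT", labeled), "leaf")
  expect_error(assemble_node_dataset(arch, arch$root,
    tibble::tibble(id = "x", class = "MOON")), "MOON")
  expect_error(assemble_node_dataset(
    arch, arch$root, labeled[labeled$class != "CYT", ]), "empty branch")
})

test_that("proteins outside a node's subtree are excluded", {
  bac <- default_topology("bacteria")
  lab <- tibble::tibble(id = sprintf("b%02d", 1:60),
                        class = rep(bac$leaves, each = 10))
  surface <- assemble_node_dataset(bac, "surface", lab)
  expect_setequal(c(surface$a_ids, surface$b_ids),
                  lab$id[lab$class %in% c("EXT", "FIM")])
})

test_that("train_node separates a symmetric two-point problem", {
  K <- diag(2); dimnames(K) <- list(c("a", "b"), c("a", "b"))
  km <- structure(list(ids = c("a", "b"), values = K,
                       self = c(a = 1, b = 1),
                       params = kernel_params(normalize = FALSE)),
                  class = "hierloc_kernel_matrix")
  nm <- train_node(km, "a", "b", regularization_c = 100)
  f <- decision_values(nm, K)
  expect_gt(f[1], 0); expect_lt(f[2], 0)
  expect_equal(abs(f[[1]]), abs(f[[2]]), tolerance = 1e-6)
})

test_that("train_node reaches zero training error on separable clusters", {
  # two tight clusters: within-similarity >> between
  n <- 10
  ids <- sprintf("x%02d", 1:(2 * n))
  K <- matrix(0.1, 2 * n, 2 * n, dimnames = list(ids, ids))
  K[1:n, 1:n] <- 0.9; K[(n + 1):(2 * n), (n + 1):(2 * n)] <- 0.9
  diag(K) <- 1
  km <- structure(list(ids = ids, values = K,
                       self = stats::setNames(rep(1, 2 * n), ids),
                       params = kernel_params()),
                  class = "hierloc_kernel_matrix")
  nm <- train_node(km, ids[1:n], ids[(n + 1):(2 * n)],
                   regularization_c = 10)
  f <- decision_values(nm, K)
  expect_true(all(f[1:n] > 0))
  expect_true(all(f[(n + 1):(2 * n)] < 0))
})

test_that("train_node rejects overlapping or empty classes", {
  K <- diag(3); ids <- c("a", "b", "c"); dimnames(K) <- list(ids, ids)
  km <- structure(list(ids = ids, values = K,
                       self = stats::setNames(rep(1, 3), ids),
                       params = kernel_params()),
                  class = "hierloc_kernel_matrix")
  expect_error(train_node(km, c("a", "b"), c("b", "c")), "both classes")
  expect_error(train_node(km, character(0), "c"), "non-empty")
})

test_that("fit_platt recovers a symmetric sigmoid on balanced data", {
  f <- c(-2, -1, -0.5, 0.5, 1, 2)
  y <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  ab <- fit_platt(f, y)
  expect_lt(ab[["a"]], 0)  # larger f means class A
  expect_equal(1 / (1 + exp(ab[["b"]])), 0.5, tolerance = 0.05)
  # probability strictly increasing in f when A-scores exceed B-scores
  p <- 1 / (1 + exp(ab[["a"]] * sort(f) + ab[["b"]]))
  expect_true(all(diff(p) > 0))
})

test_that("fit_platt matches an independent BFGS optimizer", {
  set.seed(12)
  f <- c(rnorm(10, 1.2), rnorm(10, -0.8))
  y <- rep(c(TRUE, FALSE), each = 10)
  ab <- fit_platt(f, y)
  # independent route: generic quasi-Newton on the same smoothed-target
  # cross-entropy
  n_pos <- 10; n_neg <- 10
  t <- ifelse(y, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  ref <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
  expect_equal(ab[["a"]], ref$par[1], tolerance = 1e-6)
  expect_equal(ab[["b"]], ref$par[2], tolerance = 1e-6)
})

test_that("fit_platt requires both classes", {
  expect_error(fit_platt(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("node probability and reliability behave at the boundaries", {
  nm <- structure(list(node_id = "n", platt_a = -1, platt_b = 0),
                  class = "hierloc_node_model")
  expect_equal(platt_probability(nm, 0), 0.5)
  expect_gt(platt_probability(nm, 3), 0.5)
  expect_equal(node_reliability(0.5), 0.5)
  expect_equal(node_reliability(0.93), 0.93)
  expect_equal(node_reliability(0.12), 0.88)
})

test_that("train_tree fits one calibrated model per internal node", {
  fx <- small_archaea_model()
  expect_length(fx$model$node_models, 2)
  expect_true(all(vapply(fx$model$node_models,
                         function(nm) is.finite(nm$platt_a) && nm$platt_a < 0,
                         logical(1))))
})

test_that("train_tree refuses classes too small to calibrate", {
  topo <- default_topology("archaea")
  d <- generate_dataset(synthetic_spec(topo, n_per_class = 5,
                                       seq_length = 40, seed = 31))
  d <- d[!(d$class == "EXT" & d$id != "EXT_001"), ]  # EXT left with 1
  expect_error(train_tree(d, topo, kernel_params(k = 3, sigma = 7.5)),
               "fewer than 2")
})

test_that("decision values via kernel_row match the training Gram matrix", {
  fx <- small_archaea_model()
  model <- fx$model; d <- fx$data
  gram <- kernel_matrix(stats::setNames(d$profile, d$id), model$params)
  q <- d$profile[[7]]
  row <- kernel_row(model$profiles, q, model$params)
  for (nm in model$node_models) {
    f_row <- decision_values(nm, row)
    f_gram <- decision_values(nm, gram$values[, d$id[7]])
    expect_equal(f_row, f_gram, tolerance = 1e-9)
  }
})

test_that("swapping class A and B negates f and flips the probability", {
  set.seed(41)
  ps <- lapply(1:12, function(i) random_profile(sprintf("s%02d", i), 30))
  km <- kernel_matrix(ps, kernel_params(k = 2, sigma = 3))
  a <- sprintf("s%02d", 1:6); b <- sprintf("s%02d", 7:12)
  m_ab <- train_node(km, a, b, regularization_c = 1)
  m_ba <- train_node(km, b, a, regularization_c = 1)
  f_ab <- decision_values(m_ab, km$values)
  f_ba <- decision_values(m_ba, km$values)
  expect_equal(f_ab, -f_ba, tolerance = 1e-4)
  cal <- fit_platt(f_ab, rep(c(TRUE, FALSE), each = 6))
  cal_sw <- fit_platt(f_ba, rep(c(FALSE, TRUE), each = 6))
  p <- 1 / (1 + exp(cal[["a"]] * f_ab + cal[["b"]]))
  p_sw <- 1 / (1 + exp(cal_sw[["a"]] * f_ba + cal_sw[["b"]]))
  expect_equal(p, 1 - p_sw, tolerance = 1e-4)
  expect_equal(node_reliability(p), node_reliability(p_sw),
               tolerance = 1e-4)
})

test_that("held-out node probabilities are roughly calibrated", {
  # moderately noisy two-class problem at the archaeal root
  topo <- default_topology("archaea")
  d <- generate_dataset(synthetic_spec(topo, n_per_class = 40,
                                       seq_length = 80, profile_noise = 2,
                                       seed = 61))
  d <- d[d$class %in% c("EXT", "CYT"), ]
  prm <- kernel_params(k = 5, sigma = 7.5)
  gram <- kernel_matrix(stats::setNames(d$profile, d$id), prm)
  is_tr <- rep(c(TRUE, FALSE), length.out = nrow(d))
  tr <- d[is_tr, ]; te <- d[!is_tr, ]
  nm <- train_node(gram, tr$id[tr$class == "EXT"],
                   tr$id[tr$class == "CYT"], regularization_c = 1)
  # calibrate the way the production path does: on decision values from an
  # internal cross-validation, not on training scores
  fold <- rep_len(1:3, nrow(tr))
  f_cal <- numeric(nrow(tr))
  for (fd in 1:3) {
    sub <- train_node(gram, tr$id[fold != fd & tr$class == "EXT"],
                      tr$id[fold != fd & tr$class == "CYT"],
                      regularization_c = 1)
    f_cal[fold == fd] <- decision_values(sub, gram$values[, tr$id[fold == fd],
                                                          drop = FALSE])
  }
  cal <- fit_platt(f_cal, tr$class == "EXT")
  nm$platt_a <- cal[["a"]]; nm$platt_b <- cal[["b"]]
  p_te <- platt_probability(nm, decision_values(nm, gram$values[, te$id]))
  bins <- cut(p_te, breaks = seq(0, 1, 0.1), include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    if (sum(idx) < 10) next  # tiny bins are noise
    expect_lt(abs(mean(p_te[idx]) - mean(te$class[idx] == "EXT")), 0.15)
  }
})
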