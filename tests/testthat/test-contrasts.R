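# The contrast engine: arrows, stars, signature reports, tree depths,
# habitat summaries, ordination.

test_that("arrow classes follow the percentage/significance rule", {
  expect_equal(arrow_class(6, 0.001), "↑↑")
  expect_equal(arrow_class(-3, 0.001), "↓")
  expect_equal(arrow_class(8, 0.2), "-")
  expect_equal(arrow_class(0.5, 0.001), "-")
  # boundaries: |d| = 5 -> double, |d| = 1 -> single, p = .05 significant
  expect_equal(arrow_class(5, 0.01), "↑↑")
  expect_equal(arrow_class(-5, 0.01), "↓↓")
  expect_equal(arrow_class(1, 0.05), "↑")
  expect_equal(arrow_class(-1, 0.05), "↓")
  expect_equal(arrow_class(4.99, 0.05), "↑")
  expect_equal(arrow_class(3, 0.051), "-")
  expect_true(is.na(arrow_class(NA, 0.01)))
})

test_that("arrow classes mirror when the contrast direction flips", {
  withr::local_seed(18)
  mirror <- c("↑↑" = "↓↓", "↑" = "↓",
              "-" = "-", "↓" = "↑", "↓↓" = "↑↑")
  for (i in 1:50) {
    ft <- runif(1, 0.01, 0.1)
    fr <- runif(1, 0.01, 0.1)
    p <- sample(c(0.001, 0.2), 1)
    d_fwd <- 100 * (ft - fr) / fr
    d_rev <- 100 * (fr - ft) / ft
    a_fwd <- arrow_class(d_fwd, p)
    a_rev <- arrow_class(d_rev, p)
    # sign mirrors exactly; magnitude class can differ at the band edges
    # because the denominator changes, so compare the sign only
    expect_equal(sign(d_fwd), -sign(d_rev))
    if (a_fwd == "-" && p > 0.05) expect_equal(a_rev, "-")
    if (a_fwd %in% c("↑↑", "↑")) {
      expect_true(a_rev %in% c("↓↓", "↓", "-"))
    }
  }
})

test_that("clade scheme validates contrasts against the mapping", {
  clades <- tibble::tibble(isolate_id = c("i1", "i2", "i3", "i4"),
                           clade = c("Ia", "Ib", "IIa", "IIb"))
  sch <- clade_scheme(clades)
  expect_s3_class(sch, "clade_scheme")
  expect_equal(sch$contrasts$label, c("psychrophilic", "halophilic", "thermophilic"))
  expect_error(
    clade_scheme(clades[1:2, ]),
    "absent")
})

test_that("self-contrast gives zero differences and no arrows", {
  withr::local_seed(19)
  data <- tibble::tibble(
    id = rep(sprintf("i%02d", 1:10), each = 2),
    clade = rep(c("A", "B"), each = 10),
    feature = rep(c("f1", "f2"), 10),
    value = runif(20, 1, 2))
  sch <- clade_scheme(
    tibble::tibble(isolate_id = unique(data$id),
                   clade = rep(c("A", "B"), each = 5)),
    tibble::tibble(target = "A", reference = "A", label = "self"))
  rep_self <- run_contrasts(data[data$clade == "A", ], sch, test = "rank")
  expect_true(all(rep_self$d == 0))
  expect_true(all(rep_self$arrow == "-"))

  # a constant feature is never significant
  data$value <- 1
  sch2 <- clade_scheme(
    tibble::tibble(isolate_id = unique(data$id), clade = rep(c("A", "B"), each = 5)),
    tibble::tibble(target = "B", reference = "A", label = "ab"))
  rep2 <- run_contrasts(data, sch2, test = "rank")
  expect_true(all(rep2$p_value == 1))
  expect_true(all(rep2$arrow == "-"))
})

test_that("the report carries BH-adjusted p-values alongside raw ones", {
  withr::local_seed(20)
  data <- tidyr::expand_grid(id = sprintf("i%02d", 1:12),
                             feature = paste0("f", 1:6)) |>
    dplyr::mutate(clade = rep(c("A", "B"), each = 36),
                  value = runif(72))
  sch <- clade_scheme(
    tibble::tibble(isolate_id = unique(data$id), clade = rep(c("A", "B"), each = 6)),
    tibble::tibble(target = "B", reference = "A", label = "ab"))
  out <- run_contrasts(data, sch, test = "rank")
  expect_true(all(out$p_adj >= out$p_value - 1e-12))
  expect_equal(out$p_adj, p.adjust(out$p_value, "BH"))
  # tidy/glance methods
  expect_s3_class(tidy(out), "tbl_df")
  g <- glance(out)
  expect_equal(g$n_features, 6)
})

test_that("clade leaf depths are root-to-leaf branch length sums", {
  tree <- ape::read.tree(text = "((a:0.1,b:0.2):0.1,c:0.4);")
  sch <- tibble::tibble(isolate_id = c("a", "b", "c"),
                        clade = c("X", "X", "Y"))
  out <- clade_leaf_depth(tree, sch)
  expect_equal(out$mean_depth[out$clade == "X"], 0.25)
  expect_equal(out$mean_depth[out$clade == "Y"], 0.4)
  expect_false(any(out$flag))

  zero <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  out0 <- clade_leaf_depth(zero, sch)
  expect_true(all(out0$mean_depth == 0))
  expect_false(any(out0$flag))

  expect_error(clade_leaf_depth(tree, tibble::tibble(isolate_id = "zz", clade = "X")),
               "not in tree")
})

test_that("habitat summaries average per clade with explicit n", {
  md <- tibble::tibble(
    isolate_id = sprintf("i%d", 1:6),
    clade_label = c("Ib", "Ib", "IIa", "IIa", "IIa", "Ia"),
    MAT = c(-2, -1.2, 10, 14, NA, 9),
    salinity = c(0, 1, NA, 6, 8, 0.5))
  hs <- habitat_summary(md)
  ib <- hs$subclades[hs$subclades$clade == "Ib", ]
  expect_equal(ib$mean_MAT, -1.6)
  expect_equal(ib$mean_salinity, 0.5)
  expect_equal(ib$n_salinity, 2)
  iia <- hs$subclades[hs$subclades$clade == "IIa", ]
  expect_equal(iia$n_MAT, 2)
  expect_equal(hs$major_clades$clade, c("I", "II"))
  # all-missing clade warns
  md$MAT[md$clade_label == "Ia"] <- NA
  expect_warning(habitat_summary(md), "all-missing")
})

test_that("NMDS embeds exactly embeddable configurations and separates clusters", {
  # three equidistant points embed in 2-D with ~zero stress
  ft3 <- tibble::tibble(isolate_id = c("a", "b", "c"),
                        x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2))
  ord3 <- suppressWarnings(ordinate_features(ft3, "euclidean", seed = 1))
  expect_lt(ord3$stress, 0.01)
  expect_equal(colMeans(as.matrix(ord3$points[, -1])), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)

  withr::local_seed(21)
  ft <- tibble::tibble(
    isolate_id = sprintf("i%02d", 1:12),
    f1 = c(rnorm(6, 0, 0.1), rnorm(6, 10, 0.1)),
    f2 = c(rnorm(6, 0, 0.1), rnorm(6, 10, 0.1)),
    f3 = runif(12, 0, 0.2))
  ord <- suppressWarnings(ordinate_features(ft, "euclidean", seed = 2))
  pts <- as.matrix(ord$points[, c("NMDS1", "NMDS2")])
  within_a <- max(dist(pts[1:6, ])); within_b <- max(dist(pts[7:12, ]))
  between <- min(as.matrix(dist(pts))[1:6, 7:12])
  expect_gt(between, max(within_a, within_b))

  same <- tibble::tibble(isolate_id = c("a", "b", "c"), x = 1, y = 2)
  expect_error(ordinate_features(same, "euclidean"), "zero variance")
})

test_that("signature plots build without evaluation errors", {
  withr::local_seed(22)
  data <- tidyr::expand_grid(id = sprintf("i%02d", 1:8), feature = c("f1", "f2")) |>
    dplyr::mutate(clade = rep(c("A", "B"), each = 8), value = runif(16))
  sch <- clade_scheme(
    tibble::tibble(isolate_id = unique(data$id), clade = rep(c("A", "B"), each = 4)),
    tibble::tibble(target = "B", reference = "A", label = "ab"))
  rep <- run_contrasts(data, sch, test = "rank")
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  ft3 <- tibble::tibble(isolate_id = c("a", "b", "c", "d"),
                        x = c(0, 1, 2, 4), y = c(0, 2, 1, 3))
  p2 <- autoplot(suppressWarnings(ordinate_features(ft3, "euclidean", seed = 1)))
  expect_s3_class(p2, "ggplot")
})
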