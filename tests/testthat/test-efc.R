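test_that("k-prototypes recovers a planted two-group structure exactly", {
  d <- make_two_groups(n_per = 5, sep = 10, seed = 3)
  fit <- fit_kprototypes(d[c("x", "y", "veg")], k = 2, seed = 1)
  expect_true(same_partition(fit$cluster, rep(1:2, each = 5)))
  # exhaustive-assignment oracle agrees
  oracle <- brute_force_k2(d, c("x", "y"), "veg", fit$lambda)
  expect_true(same_partition(fit$cluster, oracle$assign))
  expect_equal(fit$tot_within, oracle$obj, tolerance = 1e-8)
})

test_that("k = 1 prototype is the per-field mean / mode", {
  d <- make_two_groups(seed = 5)
  fit <- fit_kprototypes(d[c("x", "y", "veg")], k = 1, seed = 1)
  ctr <- tidy(fit)
  expect_equal(ctr$x, mean(d$x), tolerance = 1e-10)
  expect_equal(ctr$y, mean(d$y), tolerance = 1e-10)
  expect_equal(ctr$veg, names(which.max(table(d$veg))))
})

test_that("without categorical fields the partition matches Lloyd k-means", {
  set.seed(11)
  d <- tibble::tibble(x = rnorm(40, rep(c(0, 6), each = 20)),
                      y = rnorm(40, rep(c(0, 6), each = 20)))
  init <- c(3L, 25L)
  fit <- fit_kprototypes(d, 2, seed = 1, init = init)
  z <- scale(as.matrix(d))
  km <- stats::kmeans(z, centers = z[init, ], algorithm = "Lloyd",
                      iter.max = 100)
  expect_true(same_partition(fit$cluster, km$cluster))
})

test_that("degenerate clustering inputs error", {
  d <- tibble::tibble(x = rep(1, 5), veg = rep("a", 5))
  expect_error(fit_kprototypes(d, 2), "distinct")
  expect_error(fit_kprototypes(make_two_groups(2), 10), "n > k")
})

test_that("objective is non-increasing with more iterations", {
  d <- make_two_groups(n_per = 20, sep = 2, seed = 7)[c("x", "y", "veg")]
  obj <- vapply(c(1, 2, 5, 50), function(it)
    fit_kprototypes(d, 3, seed = 2, max_iter = it, n_start = 1)$tot_within,
    numeric(1))
  expect_true(all(diff(obj) <= 1e-10))
})

test_that("mixed dissimilarity with no categorical fields is squared
           Euclidean on standardized values", {
  set.seed(3)
  d <- tibble::tibble(x = rnorm(12), y = rnorm(12))
  z <- scale(as.matrix(d))
  dd <- forestcarbon:::mixed_pairwise_dist(z, NULL, 0)
  expect_equal(dd, as.matrix(dist(z))^2, tolerance = 1e-10)
})

test_that("silhouette agrees with the reference implementation and selects
           the planted number of clusters", {
  skip_if_not_installed("cluster")
  set.seed(4)
  d <- tibble::tibble(x = rnorm(30, rep(c(0, 8, 16), each = 10)),
                      y = rnorm(30, rep(c(0, 8, 16), each = 10)))
  cl <- rep(1:3, each = 10)
  mine <- silhouette_mixed(d, cl, lambda = 0)
  z <- scale(as.matrix(d))
  ref <- cluster::silhouette(cl, dmatrix = as.matrix(dist(z))^2)
  expect_equal(mine$mean, mean(ref[, "sil_width"]), tolerance = 1e-10)
  expect_true(all(mine$s >= -1 & mine$s <= 1))

  # three planted well-separated clusters -> k = 3; two -> k = 2
  d3 <- tibble::tibble(
    x = rnorm(90, rep(c(0, 8, 16), each = 30)),
    y = rnorm(90, rep(c(0, 8, 16), each = 30)),
    veg = rep(c("a", "b", "c"), each = 30))
  expect_equal(select_k(d3, 2:5, reps = 5, draw_size = 60, seed = 2)$k, 3)
  d2 <- d3[1:60, ]
  expect_equal(select_k(d2, 2:5, reps = 5, draw_size = 40, seed = 2)$k, 2)
  expect_error(select_k(d2, 2:4, reps = 2, draw_size = 1000), "draw_size")
})

test_that("raster classification is consistent with training assignments and
           recovers the planted landscape", {
  lt <- landscape_truth(nrow = 40, ncol = 40, k = 3, seed = 21)
  ls <- gen_landscape(lt)
  d <- tibble::tibble(
    veg = ls$veg$categories[as.vector(ls$veg$values)],
    elev = as.vector(ls$elev$values),
    chm = as.vector(ls$chm$values))
  fit <- fit_kprototypes(d, 3, seed = 5)
  em <- classify_raster(fit, list(elev = ls$elev, chm = ls$chm, veg = ls$veg))
  # training cells keep their fitted labels
  expect_equal(as.vector(em$labels$values), fit$cluster)
  # >= 99% agreement with generating truth up to label permutation
  tab <- table(as.vector(em$labels$values), as.vector(ls$labels$values))
  expect_gte(sum(apply(tab, 2, max)) / sum(tab), 0.99)

  # a cell equal to a prototype classifies to that prototype
  proto1 <- tidy(fit)[1, ]
  stack1 <- list(
    elev = grid_raster(matrix(proto1$elev, 1, 1)),
    chm = grid_raster(matrix(proto1$chm, 1, 1)),
    veg = grid_raster(matrix(match(proto1$veg, ls$veg$categories), 1, 1),
                      categories = ls$veg$categories))
  expect_equal(as.vector(classify_raster(fit, stack1)$labels$values), 1)

  expect_error(classify_raster(fit, list(elev = ls$elev)), "missing fields")
})

test_that("forest masking removes area and only area", {
  lab <- matrix(rep(1:2, each = 8), 4, 4)
  em <- make_efc_map(lab)
  all_forest <- grid_raster(matrix(2, 4, 4),
                            categories = c("non_forest", "forest"))
  em2 <- apply_forest_mask(em, all_forest)
  expect_equal(em2$labels$values, em$labels$values)
  expect_equal(em2$areas, em$areas)

  none <- grid_raster(matrix(1, 4, 4), categories = c("non_forest", "forest"))
  expect_true(all(apply_forest_mask(em, none)$areas$area_ha == 0))

  checker <- grid_raster(matrix(rep(c(1, 2), 8), 4, 4),
                         categories = c("non_forest", "forest"))
  em3 <- apply_forest_mask(em, checker)
  expect_equal(em3$areas$area_ha, em$areas$area_ha / 2)

  # area bookkeeping: sum of label areas = labelled cells x cell area
  cell_ha <- 30^2 / 1e4
  expect_equal(sum(em3$areas$area_ha),
               sum(!is.na(em3$labels$values)) * cell_ha)
  expect_error(apply_forest_mask(em, all_forest, forest_classes = character(0)),
               "forest classes")
})

test_that("constellation grouping follows connectivity and the area floor", {
  # two blobs separated by no-data; cell = 30 m -> 0.09 ha
  lab <- matrix(NA_real_, 10, 10)
  lab[1:4, 1:4] <- 1      # 16 cells = 1.44 ha
  lab[7:10, 7:10] <- 2    # 16 cells = 1.44 ha
  em <- make_efc_map(lab, k = 2)
  out <- group_constellations(em, min_area_ha = 1)
  ids <- out$constellations$values
  expect_equal(length(unique(stats::na.omit(as.vector(ids)))), 2)
  # below the floor -> unassigned
  out2 <- group_constellations(em, min_area_ha = 2)
  expect_true(all(is.na(out2$constellations$values)))
  # one blob with two labels -> one constellation with 2 EFCs
  lab3 <- matrix(rep(1:2, each = 50), 10, 10)
  out3 <- group_constellations(make_efc_map(lab3, 2), min_area_ha = 1)
  expect_equal(nrow(out3$constellation_summary), 1)
  expect_equal(out3$constellation_summary$n_efcs, 2)
  # diagonal contact is connected under 8-connectivity
  lab4 <- matrix(NA_real_, 4, 4)
  lab4[1, 1] <- 1; lab4[2, 2] <- 1
  out4 <- group_constellations(make_efc_map(lab4, 1), min_area_ha = 0.1)
  expect_equal(length(unique(stats::na.omit(as.vector(
    out4$constellations$values)))), 1)
})

test_that("class-mapping files round-trip", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(source_class = c("nb1", "nb2"),
                       functional_group = c("evergreen", "evergreen")),
            path, row.names = FALSE)
  m <- read_class_mapping(path)
  expect_equal(unname(m["nb1"]), "evergreen")
})
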