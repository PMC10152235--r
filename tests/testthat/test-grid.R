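cells_df <- function(x, y, class = "cancer") {
  data.frame(cell_id = seq_along(x), x_um = x, y_um = y, class = class)
}

test_that("rasterize bins cells with the half-open convention", {
  spec <- grid_spec(0, 0, 50, n_cols = 2, n_rows = 2)
  lat <- rasterize(cells_df(25, 25), spec)
  expect_equal(lat$cancer[1, 1], 1L)
  expect_equal(sum(lat$cancer), 1L)
  # a cell exactly on the x = 50 boundary goes to the second column
  lat2 <- rasterize(cells_df(50, 10), spec)
  expect_equal(lat2$cancer[1, 2], 1L)
  expect_equal(lat2$cancer[1, 1], 0L)
})

test_that("rasterize validates inputs and reports out-of-bounds counts", {
  spec <- grid_spec(0, 0, 50, 2, 2)
  expect_error(rasterize(cells_df(c(10, 120, 130), c(10, 10, 10)), spec),
               "2 cell")
  expect_error(rasterize(cells_df(NA, 1), spec), "finite")
  expect_error(rasterize(cells_df(1, 1, class = "mystery"), spec),
               "mystery")
})

test_that("channel sums are conserved against per-cell binning", {
  set.seed(14)
  n <- 1000
  cls <- sample(c("cancer", "lymphocyte", "stromal"), n, replace = TRUE)
  cells <- cells_df(runif(n, 0, 777), runif(n, 0, 555), cls)
  spec <- grid_spec_for(cells)
  lat <- rasterize(cells, spec)
  expect_equal(sum(lat$cancer), sum(cls == "cancer"))
  expect_equal(sum(lat$lymphocyte), sum(cls == "lymphocyte"))
  # brute-force per-cell binning oracle
  for (i in sample(n, 25)) {
    row <- floor((cells$y_um[i] - spec$y0) / spec$g) + 1
    col <- floor((cells$x_um[i] - spec$x0) / spec$g) + 1
    expect_true(lat$tissue[row, col])
  }
  # tissue flag counts every class, including ignored stromal
  expect_equal(sum(lat$tissue),
               length(unique(paste(floor(cells$x_um / 50),
                                   floor(cells$y_um / 50)))))
})

test_that("neighborhood sizes match queen-contiguity enumeration", {
  spec <- grid_spec(0, 0, 50, 11, 11)
  w1 <- build_neighbors(spec, 1, include_self = FALSE)
  center <- 6 + 5 * 11
  expect_length(w1$neighbors[[center]], 8)
  expect_length(w1$neighbors[[1]], 3)            # corner
  expect_length(w1$neighbors[[2]], 5)            # edge
  w4 <- build_neighbors(spec, 4, include_self = FALSE)
  expect_length(w4$neighbors[[center]], 80)      # 9x9 window minus center
  w4s <- build_neighbors(spec, 4, include_self = TRUE)
  expect_length(w4s$neighbors[[center]], 81)
  # symmetry: j in N(i) <=> i in N(j)
  for (i in sample(121, 10)) {
    for (j in w4$neighbors[[i]]) expect_true(i %in% w4$neighbors[[j]])
  }
})

test_that("getis_ord matches the loop oracle on a center-spike lattice", {
  M <- matrix(0L, 21, 21); M[11, 11] <- 100L
  lat <- structure(list(spec = grid_spec(0, 0, 50, 21, 21), cancer = M,
                        lymphocyte = M * 0L,
                        tissue = matrix(TRUE, 21, 21)),
                   class = "count_lattice")
  w <- build_neighbors(lat$spec, 4, TRUE)
  gi <- getis_ord(lat, w, "cancer")
  zo <- gi_loop_oracle(lat, "cancer", 4, TRUE)
  expect_lt(max(abs(gi$z - zo), na.rm = TRUE), 1e-9)
  expect_true(gi$z[11, 11] > 0 && gi$p[11, 11] < 0.05)
  # far corner is below the mean locally
  expect_lt(gi$z[1, 1], 0)
})

test_that("getis_ord handles degenerate and self-exclusion cases", {
  M <- matrix(5L, 8, 8)
  lat <- structure(list(spec = grid_spec(0, 0, 50, 8, 8), cancer = M,
                        lymphocyte = M, tissue = matrix(TRUE, 8, 8)),
                   class = "count_lattice")
  w <- build_neighbors(lat$spec, 2, TRUE)
  gi <- getis_ord(lat, w, "cancer")
  expect_true(all(is.na(gi$z)))                   # S = 0: z undefined
  expect_true(all(gi$p == 1))                     # and nothing significant
  # Gi (self excluded) also matches its loop oracle
  set.seed(4)
  M2 <- matrix(rpois(64, 3), 8, 8)
  lat$cancer <- M2
  wx <- build_neighbors(lat$spec, 2, include_self = FALSE)
  gi2 <- getis_ord(lat, wx, "cancer")
  zo2 <- gi_loop_oracle(lat, "cancer", 2, include_self = FALSE)
  expect_lt(max(abs(gi2$z - zo2), na.rm = TRUE), 1e-9)
})

test_that("getis_ord is invariant to an all-zero non-tissue border", {
  set.seed(8)
  M <- matrix(rpois(100, 2), 10, 10)
  mk <- function(M, tissue) structure(
    list(spec = grid_spec(0, 0, 50, ncol(M), nrow(M)), cancer = M,
         lymphocyte = M * 0L, tissue = tissue), class = "count_lattice")
  lat <- mk(M, matrix(TRUE, 10, 10))
  Mb <- matrix(0L, 14, 14); Mb[3:12, 3:12] <- M
  tb <- matrix(FALSE, 14, 14); tb[3:12, 3:12] <- TRUE
  latb <- mk(Mb, tb)
  w <- build_neighbors(lat$spec, 3, TRUE)
  wb <- build_neighbors(latb$spec, 3, TRUE)
  z <- getis_ord(lat, w, "cancer")$z
  zb <- getis_ord(latb, wb, "cancer")$z
  expect_equal(z, zb[3:12, 3:12], tolerance = 1e-12)
})

test_that("increasing a grid's count never decreases its own z", {
  set.seed(77)
  for (r in 1:20) {
    nr <- sample(6:12, 1); nc <- sample(6:12, 1)
    M <- matrix(rpois(nr * nc, 2), nr, nc)
    lat <- structure(list(spec = grid_spec(0, 0, 50, nc, nr), cancer = M,
                          lymphocyte = M * 0L,
                          tissue = matrix(TRUE, nr, nc)),
                     class = "count_lattice")
    w <- build_neighbors(lat$spec, 2, TRUE)
    z0 <- getis_ord(lat, w, "cancer")$z
    i <- sample(nr * nc, 1)
    lat$cancer[i] <- lat$cancer[i] + 1L
    z1 <- getis_ord(lat, w, "cancer")$z
    expect_gte(z1[i], z0[i] - 1e-9)
  }
})

test_that("compartment labels implement the p-value rules", {
  mkgi <- function(p) list(z = qnorm(p, lower.tail = FALSE), p = p)
  tissue <- matrix(TRUE, 1, 4)
  pc <- matrix(c(0.01, 0.20, 0.01, 0.50), 1, 4)
  pl <- matrix(c(0.20, 0.01, 0.01, 0.50), 1, 4)
  map <- label_compartments(mkgi(pc), mkgi(pl), tissue, alpha = 0.05)
  expect_equal(as.vector(map$label), c("CH", "IH_peri", "IH_intra", "NONE"))
  # ties at exactly alpha are non-significant (strict <)
  pc2 <- matrix(0.05, 1, 1); pl2 <- matrix(0.01, 1, 1)
  map2 <- label_compartments(mkgi(pc2), mkgi(pl2), matrix(TRUE, 1, 1))
  expect_equal(as.vector(map2$label), "IH_peri")
  # non-tissue grids are NONE regardless of p
  map3 <- label_compartments(mkgi(pc2 * 0 + 0.001), mkgi(pl2),
                             matrix(FALSE, 1, 1))
  expect_equal(as.vector(map3$label), "NONE")
})

test_that("spatial scores reproduce hand-computed fractions", {
  lab <- matrix("NONE", 10, 10)
  lab[1, 1:2] <- "IH_intra"; lab[2, 1:6] <- "IH_peri"; lab[3, 1:8] <- "CH"
  map <- structure(list(label = lab, tissue = matrix(TRUE, 10, 10)),
                   class = "hotspot_label_map")
  sc <- spatial_scores(map)
  expect_equal(sc$s_intra_immune, 0.25)
  expect_equal(sc$s_intra_cancer, 0.20)
  expect_equal(sc$s_intra_tissue, 0.02)
  # empty numerator and saturation
  lab2 <- lab; lab2[lab2 == "IH_intra"] <- "NONE"
  sc2 <- spatial_scores(structure(list(label = lab2,
                                       tissue = matrix(TRUE, 10, 10)),
                                  class = "hotspot_label_map"))
  expect_equal(sc2$s_intra_immune, 0)
  lab3 <- lab; lab3[lab3 == "IH_peri"] <- "NONE"
  sc3 <- spatial_scores(structure(list(label = lab3,
                                       tissue = matrix(TRUE, 10, 10)),
                                  class = "hotspot_label_map"))
  expect_equal(sc3$s_intra_immune, 1)
  # zero denominator -> NA with reason
  lab4 <- matrix("NONE", 4, 4)
  sc4 <- spatial_scores(structure(list(label = lab4,
                                       tissue = matrix(TRUE, 4, 4)),
                                  class = "hotspot_label_map"))
  expect_true(is.na(sc4$s_intra_immune))
  expect_named(sc4$undefined, c("s_intra_immune", "s_intra_cancer"))
})

test_that("labels partition the tissue grids", {
  cells <- generate_slide(demo_slide_config(4))
  map <- hotspot_map(cells)
  sc <- spatial_scores(map)
  n_none_tissue <- sum(map$label == "NONE" & map$tissue)
  expect_equal(sc$n_ch + sc$n_ih_peri + sc$n_ih_intra + n_none_tissue,
               sc$n_tissue)
  # no label outside tissue
  expect_true(all(map$label[!map$tissue] == "NONE"))
})
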