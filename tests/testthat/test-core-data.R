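test_that("genotype table validation rejects malformed input", {
  df <- tibble::tibble(individual_id = c("a", "b"), population_id = "p1",
                       l1_a1 = c(1L, 2L), l1_a2 = c(1L, NA))
  expect_error(genotype_table(df), "half-called")
  df2 <- tibble::tibble(individual_id = c("a", "a"), population_id = "p1",
                        l1_a1 = 1L, l1_a2 = 1L)
  expect_error(genotype_table(df2), "duplicate individual_id")
  df3 <- tibble::tibble(individual_id = "a", population_id = "p1",
                        behaviour = "nomad", l1_a1 = 1L, l1_a2 = 1L)
  expect_error(genotype_table(df3), "behaviour")
  df4 <- tibble::tibble(individual_id = c("a", "b"), population_id = "p1",
                        x = c(0, Inf), y = 0, l1_a1 = 1L, l1_a2 = 1L)
  expect_error(genotype_table(df4, require_coords = TRUE), "non-finite")
})

test_that("Genepop parsing handles 2/3-digit codes, missing and malformed lines", {
  gp <- c("title line", "locA", "locB", "pop",
          "ind1 , 001002 003003", "ind2 , 000000 003004",
          "pop", "ind3 , 002002 004004")
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(gp, f)
  g <- read_genotypes(f, format = "genepop")
  expect_equal(nrow(g), 3)
  expect_equal(loci(g), c("locA", "locB"))
  expect_equal(unique(g$population_id), c("pop1", "pop2"))
  expect_true(is.na(g$locA_a1[2]))           # "000000" is missing
  expect_equal(g$locA_a1[1], 1L)
  expect_equal(g$locB_a2[2], 4L)

  bad <- c("t", "locA", "pop", "ind1 , 0010")   # 4 digits ok; now a bad one
  writeLines(c("t", "locA", "pop", "ind1 , 00100"), f)
  expect_error(read_genotypes(f, format = "genepop"), "malformed allele code")
  writeLines(c("t", "locA", "pop", "ind1 , 001000"), f)
  expect_error(read_genotypes(f, format = "genepop"), "half-missing")
})

test_that("genotype CSV and Genepop round trips reproduce the table", {
  for (seed in 1:3) {
    g <- random_genotypes(n = 8, L = 4, n_pops = 2, seed = seed,
                          missing_rate = 0.1)
    f <- withr::local_tempfile(fileext = ".csv")
    write_genotypes(g, f, format = "csv")
    g2 <- read_genotypes(f, format = "csv")
    expect_equal(loci(g2), loci(g))
    expect_equal(as.data.frame(g2)[names(g)], as.data.frame(g)[names(g)],
                 tolerance = 1e-9)
    # Genepop carries alleles + population blocks only
    f2 <- withr::local_tempfile(fileext = ".gen")
    grp <- g[order(g$population_id), ]
    grp <- genotype_table(grp, loci = loci(g))
    write_genotypes(grp, f2, format = "genepop")
    g3 <- read_genotypes(f2, format = "genepop")
    expect_equal(loci(g3), loci(g))
    for (l in loci(g)) {
      expect_equal(g3[[paste0(l, "_a1")]], grp[[paste0(l, "_a1")]])
      expect_equal(g3[[paste0(l, "_a2")]], grp[[paste0(l, "_a2")]])
    }
  }
})

test_that("distance matrix CSV round trip is exact and rejects asymmetry", {
  z <- dist_mat(matrix(0, 2, 2), kind = "other", labels = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix(z, f)
  expect_equal(unclass(read_matrix(f)), unclass(z))

  set.seed(42)
  for (rep in 1:3) {
    v <- matrix(rnorm(100), 10, 10)
    v <- v + t(v); diag(v) <- 0
    m <- dist_mat(v, kind = "other")
    write_matrix(m, f)
    m2 <- read_matrix(f)
    expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)
    expect_identical(dm_kind(m2), "other")
  }

  writeLines(c("label,a,b", "a,0,1", "b,2,0"), f)
  expect_error(read_matrix(f), "asymmetric")
})

test_that("dist_mat enforces its kind invariants", {
  v <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(dist_mat(v, kind = "euclidean"), "non-negative")
  expect_error(dist_mat(matrix(c(0, 2, 2, 0), 2, 2), kind = "relatedness"),
               "\\[0, 1\\]")
  expect_error(dist_mat(matrix(c(0, 1, 2, 0), 2, 2)), "not symmetric")
  expect_error(dist_mat(matrix(0, 2, 2), labels = c("a", "a")), "duplicate")
})

test_that("ESRI ASCII grid round trip, no-data masking and validation", {
  s <- resistance_surface(matrix(c(1, 2, 3, 4, NA, 6, 7, 8, 9), 3, 3,
                                 byrow = TRUE),
                          cell_size = 30, origin_x = 100, origin_y = 200)
  f <- withr::local_tempfile(fileext = ".asc")
  write_resistance(s, f)
  s2 <- read_resistance(f)
  expect_equal(s2$values, s$values)
  expect_equal(s2$cell_size, 30)
  expect_equal(s2$origin_x, 100)
  expect_true(is.na(s2$values[2, 2]))

  expect_error(resistance_surface(matrix(c(1, -1, 1, 1), 2, 2), 30),
               "non-positive")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 30", "NODATA_value -9999", "1 1 1"), f)
  expect_error(read_resistance(f), "rows")
  writeLines(c("ncols 3", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 30", "NODATA_value -9999", "1 1"), f)
  expect_error(read_resistance(f), "columns")
})

test_that("GeoJSON barrier features parse with multi-part handling", {
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(),
         geometry = list(type = "LineString",
                         coordinates = list(list(0, 0), list(10, 10)))),
    list(type = "Feature", properties = list(),
         geometry = list(type = "Polygon",
                         coordinates = list(list(list(0, 0), list(5, 0),
                                                 list(5, 5), list(0, 5),
                                                 list(0, 0)))))
  ))
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE)
  b <- read_barriers(f, class = "roads")
  expect_length(b$features, 2)
  expect_equal(b$geometry, c("polyline", "polygon"))
  expect_equal(nrow(b$features[[2]]), 4)   # closing vertex dropped
  expect_equal(b$feature_id, c(1L, 2L))
})

test_that("population attributes validate sizes and centroids", {
  ok <- tibble::tibble(population_id = c("a", "b"), n_census = c(100L, 50L),
                       n_effective = c(30.5, 12.2), centroid_x = c(0, 1),
                       centroid_y = c(0, 1))
  expect_silent(population_attributes(ok))
  bad <- ok; bad$n_effective[1] <- -2
  expect_error(population_attributes(bad), "n_effective")
  bad2 <- ok; bad2$centroid_x[2] <- NaN
  expect_error(population_attributes(bad2), "centroid")
})
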