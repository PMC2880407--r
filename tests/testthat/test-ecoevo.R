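test_that("habitat correlation recovers monotone trends and rejects
           degenerate factors", {
  meas <- data.frame(species_id = paste0("s", 1:5),
                     idaa = c(0.35, 0.30, 0.25, 0.20, 0.15))
  hab <- data.frame(species_id = paste0("s", 1:5),
                    optimal_temperature_c = c(20, 40, 60, 80, 100))
  r <- disorderVsEnvironment(meas, hab, "optimal_temperature_c", "idaa")
  expect_equal(r$spearman_rho, -1)
  expect_equal(r$pearson_r, -1, tolerance = 1e-12)
  expect_lt(r$slope, 0)
  hab$optimal_temperature_c <- 50
  expect_error(disorderVsEnvironment(meas, hab, "optimal_temperature_c"),
               "zero variance")
  expect_error(disorderVsEnvironment(meas[1:2, ], hab[1:2, ],
                                     "optimal_temperature_c"),
               "insufficient species")
})

test_that("categorical salinity is rank-coded low < normal < high", {
  meas <- data.frame(species_id = paste0("s", 1:6),
                     idaa = c(0.1, 0.12, 0.2, 0.22, 0.3, 0.32))
  hab <- data.frame(species_id = paste0("s", 1:6),
                    salinity = c("low", "low", "normal", "normal",
                                 "high", "high"))
  r <- disorderVsEnvironment(meas, hab, "salinity", "idaa")
  expect_gt(r$pearson_r, 0.9)
  # species ordering must not matter
  sh <- sample(1:6)
  r2 <- disorderVsEnvironment(meas[sh, ], hab[rev(sh), ], "salinity")
  expect_equal(r2$pearson_r, r$pearson_r, tolerance = 1e-12)
})

test_that("measure correlation reports exact fits for linear toy data", {
  meas <- data.frame(species_id = paste0("s", 1:4),
                     idaa = c(0.1, 0.2, 0.3, 0.4),
                     idp30 = 2 * c(0.1, 0.2, 0.3, 0.4),
                     widp = 0.5 - c(0.1, 0.2, 0.3, 0.4))
  mc <- measureCorrelation(meas)
  row1 <- mc[mc$x == "idaa" & mc$y == "idp30", ]
  expect_equal(row1$pearson_r, 1, tolerance = 1e-12)
  expect_equal(row1$slope, 2, tolerance = 1e-12)
  row2 <- mc[mc$x == "idaa" & mc$y == "widp", ]
  expect_equal(row2$pearson_r, -1, tolerance = 1e-12)
})

test_that("disorder color bins follow the strict > thresholds and
           partition [0, 100]", {
  expect_equal(disorderColorBin(32), "red")
  expect_equal(disorderColorBin(18), "yellow")
  expect_equal(disorderColorBin(14), "dark_blue")
  expect_equal(disorderColorBin(20.5), "yellow")
  expect_equal(disorderColorBin(21), "yellow")
  expect_equal(disorderColorBin(30), "orange")
  expect_equal(disorderColorBin(17), "light_blue")
  grid <- seq(0, 100, by = 0.25)
  bins <- disorderColorBin(grid)
  expect_false(anyNA(bins))
  expect_setequal(unique(bins), c("red", "orange", "yellow", "light_blue",
                                  "dark_blue"))
  # each bin is a contiguous interval
  expect_equal(rle(bins)$values, c("dark_blue", "light_blue", "yellow",
                                   "orange", "red"))
  expect_error(disorderColorBin(120), "percent")
})

test_that("tree annotation colors known leaves and preserves topology", {
  nwk <- "(speciesA:1,(speciesB:1,speciesC:1):0.5);"
  idaaPct <- c(speciesA = 32, speciesB = 14, speciesC = 18)
  at <- annotateTree(nwk, idaaPct)
  expect_equal(at$annotation$color[at$annotation$leaf == "speciesA"], "red")
  expect_equal(at$annotation$color[at$annotation$leaf == "speciesB"],
               "dark_blue")
  expect_equal(at$annotation$color[at$annotation$leaf == "speciesC"],
               "yellow")
  # topology untouched: round-trip Newick comparison
  expect_equal(ape::write.tree(at$tree),
               ape::write.tree(ape::read.tree(text = nwk)))
})

test_that("missing leaves are tolerated or strict, malformed trees error", {
  nwk <- "(speciesA:1,speciesB:1);"
  at <- annotateTree(nwk, c(speciesA = 10), strict = FALSE)
  expect_true(is.na(at$annotation$color[at$annotation$leaf == "speciesB"]))
  expect_error(annotateTree(nwk, c(speciesA = 10), strict = TRUE),
               "unannotated leaf 'speciesB'")
  expect_error(annotateTree("(((", c(a = 1)), "parse error")
})

test_that("annotated tree export carries colors as leaf comments", {
  nwk <- "(speciesA:1,(speciesB:1,speciesC:1):0.5);"
  at <- annotateTree(nwk, c(speciesA = 32, speciesB = 14, speciesC = 18))
  f <- tempfile(fileext = ".nwk")
  writeAnnotatedTree(at, f)
  out <- readLines(f)
  expect_match(out, "speciesA\\[&color=red\\]")
  expect_match(out, "speciesB\\[&color=dark_blue\\]")
  side <- read.delim(paste0(f, ".tsv"))
  expect_equal(nrow(side), 3L)
  expect_equal(sort(side$color), c("dark_blue", "red", "yellow"))
})

test_that("habitat tables are validated on read", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("species_id\toptimal_ph\toptimal_temperature_c\tsalinity\tflags",
               "s1\t7\t80\tnormal\t", "s2\tNA\t30\thigh\tsymbiont"), f)
  h <- readHabitats(f)
  expect_equal(nrow(h), 2L)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("species_id\toptimal_ph", "s1\t15"), bad)
  expect_error(readHabitats(bad), "optimal_ph")
})
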