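test_that("a minimal census CSV reads into a validated table", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,x_km,y_km,year,abundance",
               "a,5,5,2000,1", "a,5,5,2008,0", "a,5,5,2018,2"), p)
  cen <- read_census_csv(p)
  expect_s3_class(cen, "census_table")
  expect_identical(cen$years, c(2000L, 2008L, 2018L))
  expect_identical(as.vector(cen$counts), c(1L, 0L, 2L))
})

test_that("malformed census CSVs are rejected with a pointed message", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,x_km,y_km,abundance", "a,5,5,1"), p)
  expect_error(read_census_csv(p), "year")
  writeLines(c("cell_id,x_km,y_km,year,abundance",
               "a,5,5,2000,1", "a,5,5,2000,2"), p)
  expect_error(read_census_csv(p), "duplicated")
  writeLines(c("cell_id,x_km,y_km,year,abundance",
               "a,5,5,2000,1", "b,15,5,2000,-2"), p)
  expect_error(read_census_csv(p), "row 2")
  writeLines(c("cell_id,x_km,y_km,year,abundance",
               "a,5,5,2000,1.5"), p)
  expect_error(read_census_csv(p), "non-integer")
})

test_that("write/read round-trip reproduces a 50-cell census exactly", {
  set.seed(42)
  counts <- matrix(rpois(150, 1.3), 50, 3)
  cen <- make_census(counts, years = c(2000, 2008, 2018))
  p <- withr::local_tempfile(fileext = ".csv")
  write_census_csv(cen, p)
  back <- read_census_csv(p)
  expect_identical(back$counts, cen$counts[order(cen$cells$cell_id), ])
  expect_equal(back$cells[order(back$cells$cell_id), ],
               cen$cells[order(cen$cells$cell_id), ],
               ignore_attr = TRUE)
})

test_that("downstream results do not depend on CSV row order", {
  set.seed(7)
  cen <- make_census(matrix(rpois(90, 1), 30, 3), years = 2000:2002)
  p <- withr::local_tempfile(fileext = ".csv")
  write_census_csv(cen, p)
  d <- read.csv(p)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(d[sample(nrow(d)), ], p2, row.names = FALSE, quote = FALSE)
  expect_identical(read_census_csv(p)$counts, read_census_csv(p2)$counts)
})

test_that("ever-present filter keeps exactly the once-occupied cells", {
  counts <- rbind(c(0, 0, 0), c(0, 1, 0), c(2, 0, 1))
  cen <- make_census(counts, years = 2000:2002)
  f <- filter_ever_present(cen)
  expect_identical(nrow(f$counts), 2L)
  expect_false(cen$cells$cell_id[1] %in% f$cells$cell_id)
  expect_true(cen$cells$cell_id[2] %in% f$cells$cell_id)
  # idempotent
  expect_identical(filter_ever_present(f)$counts, f$counts)
  # all-empty census is an error
  expect_error(filter_ever_present(make_census(matrix(0L, 4, 2))),
               "no cell")
})

test_that("filter size bookkeeping matches the generator's forced-empty count", {
  cfg <- synth_config(nx = 10, ny = 10, never_occupied_frac = 0.2, seed = 9)
  s <- simulate_census(cfg)
  k <- length(s$truth$never_occupied)
  expect_identical(k, 20L)
  kept <- filter_ever_present(s$census)
  # forced-empty cells are certainly dropped; others only if all-zero by chance
  expect_true(nrow(kept$cells) <= 100L - k)
  expect_false(any(s$truth$never_occupied %in% kept$cells$cell_id))
})

test_that("GeoJSON export writes centred square polygons with attributes", {
  p <- withr::local_tempfile(fileext = ".geojson")
  cells <- data.frame(cell_id = "a", x_km = 5, y_km = 5)
  write_geojson(cells, NULL, p)
  gj <- jsonlite::read_json(p)
  expect_identical(gj$type, "FeatureCollection")
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  xy <- do.call(rbind, lapply(ring, unlist))
  expect_equal(range(xy[, 1]), c(0, 10))
  expect_equal(range(xy[, 2]), c(0, 10))
  expect_identical(ring[[1]], ring[[5]])  # closed ring

  cells4 <- lattice_cells(2, 2)
  att <- data.frame(cell_id = cells4$cell_id,
                    class = c("High", "Low", "NS", "NS"))
  write_geojson(cells4, att, p)
  gj <- jsonlite::read_json(p)
  expect_length(gj$features, 4)
  expect_identical(vapply(gj$features, function(f) f$properties$class, ""),
                   att$class)
  expect_error(write_geojson(cells4, data.frame(cell_id = "zz", v = 1), p),
               "unknown cell_id")
})

test_that("change table is exact integer bookkeeping", {
  counts <- cbind(c(1, 0, 2), c(0, 3, 2))
  cen <- make_census(counts, years = c(2000, 2008))
  ch <- change_table(cen)
  expect_identical(ch$abundance_change, 2L)  # 5 - 3
  expect_identical(ch$occupancy_change, 0L)  # 2 - 2
})
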