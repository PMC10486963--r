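# shared fixture builders (everything generated in code, no stored data)

lattice_cells <- function(nx, ny, s = 10) {
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  data.frame(cell_id = sprintf("c%03d", seq_len(nrow(g))),
             x_km = (g$ix - 0.5) * s, y_km = (g$iy - 0.5) * s)
}

# census on an nx x ny lattice from a counts matrix (cells x years)
make_census <- function(counts, years = seq_len(ncol(counts)), nx = NULL,
                        s = 10) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(nx)) nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  cells <- lattice_cells(nx, ny, s)[seq_len(n), ]
  census_table(cells, years, counts)
}

# the published census scale: totals 1270/1364/1372 pairs over
# 700/725/731 occupied cells of 1033; per-cell layout is arbitrary
# (only totals and occupancy matter for the change bookkeeping)
paper_scale_census <- function() {
  n <- 1033L
  totals <- c(1270L, 1364L, 1372L)
  occupied <- c(700L, 725L, 731L)
  counts <- matrix(0L, n, 3)
  for (j in 1:3) {
    counts[seq_len(occupied[j]), j] <- 1L
    counts[1L, j] <- counts[1L, j] + (totals[j] - occupied[j])
  }
  make_census(counts, years = c(2000L, 2008L, 2018L), nx = 40)
}
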