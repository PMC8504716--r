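# Shared fixtures and independent oracles.

# Seed trial: all-cause mortality of the 2:1 Empa-REG-Outcome design.
seed_table <- function() trial_table(a = 194, b = 269, c = 2139, d = 4418)

# Perfect trial: only responders enrolled; control arm all deceased.
perfect_table <- function() trial_table(a = 60, b = 0, c = 0, d = 121)

# Random valid 2x2 tables with all margins positive.
random_tables <- function(n, seed = 42, max_cell = 500) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      cells <- sample.int(max_cell, 4, replace = TRUE)
      m <- matrix(cells, 2)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
        return(trial_table(a = cells[1], b = cells[2],
                           c = cells[3], d = cells[4]))
      }
    }
  })
}

# Brute-force Pearson chi-square: explicit expected counts, cell by cell.
# Independent of the package's route through chisq.test.
oracle_chi2 <- function(tab) {
  o <- c(tab$a, tab$b, tab$c, tab$d)
  N <- sum(o)
  row_tot <- c(tab$a + tab$b, tab$c + tab$d)
  col_tot <- c(tab$Nc, tab$NT)
  e <- c(row_tot[1] * col_tot[1], row_tot[1] * col_tot[2],
         row_tot[2] * col_tot[1], row_tot[2] * col_tot[2]) / N
  sum((o - e)^2 / e)
}
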