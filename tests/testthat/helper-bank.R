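# Shared fixtures: the packaged bank (both raw and transformed) and a small
# well-behaved toy bank for cases where negative slopes would only obscure
# the property under test.

ctt_bank <- load_station_checklists()
bank_2pl <- ctt_to_2pl(ctt_bank)

toy_bank <- function(n_stations = 2, items = 5, a = 1, b = 0) {
  out <- data.frame(station = rep(seq_len(n_stations), each = items),
                    item = rep(seq_len(items), times = n_stations),
                    a = a, b = b)
  class(out) <- c("item_params", "data.frame")
  out
}

# Brute-force theta MLE: dense grid search over [-4, 4]
grid_theta <- function(u, bank, D = 1.702, n_grid = 4001) {
  grid <- seq(-4, 4, length.out = n_grid)
  ll <- vapply(grid, function(th) {
    p <- prob_correct(th, bank$a, bank$b, D = D)
    sum(u * log(p) + (1 - u) * log(1 - p))
  }, numeric(1))
  grid[which.max(ll)]
}
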