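# Shared fixtures: small noiseless / noisy synthetic fields and a
# nearest-centroid matcher from detected cells to ground-truth cells.

small_config <- function(seed = 3, ...) {
  simulation_config(n_cells = 40, image_size = 300, seed = seed,
                    read_noise_sd = 0, shot_noise = FALSE, ...)
}

noisy_config <- function(seed = 3, ...) {
  simulation_config(n_cells = 40, image_size = 300, seed = seed, ...)
}

# detected cell id -> ground-truth cell id, by nearest nucleus centroid
match_truth <- function(truth, cells) {
  ct <- cell_table(cells)
  vapply(seq_len(nrow(ct)), function(i) {
    which.min((truth$nucleus_row - ct$nucleus_row[i])^2 +
                (truth$nucleus_col - ct$nucleus_col[i])^2)
  }, integer(1))
}

# brute-force Spearman: rank both vectors, then Pearson on the ranks
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

curve_4pl <- function(x, bottom, top, x_half, hill) {
  bottom + (top - bottom) / (1 + (x / x_half)^hill)
}
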