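# Published error matrices for the two classification epochs, frozen from
# their printed cells (rows = classified, columns = reference; class order
# water, mangrove, bare/built-up, other vegetation). Marginal totals are
# never taken from the source table.

lulc_classes <- c("water", "mangrove", "bare_builtup", "other_vegetation")

epoch1_error_matrix <- function() {
  confusion_matrix(rbind(
    c(81,   0,  0,   0),
    c( 0, 647,  0,   0),
    c( 0,   1, 26,   5),
    c( 0,   1,  0, 944)), lulc_classes)
}

epoch2_error_matrix <- function() {
  confusion_matrix(rbind(
    c(81,   0,  0,   0),
    c( 0, 642,  1,   4),
    c( 0,   0, 32,   0),
    c( 0,   9,  0, 936)), lulc_classes)
}

# independent brute-force decomposition of a confusion matrix: per-class
# quantity components summed directly, allocation as the remainder
oracle_disagreement <- function(counts) {
  q <- 0
  for (g in seq_len(nrow(counts)))
    q <- q + abs(sum(counts[g, ]) - sum(counts[, g]))
  Q <- q / 2
  D <- sum(counts) - sum(diag(counts))
  c(Q = Q, A = D - Q, D = D)
}

# conventional half-up rounding, the presentation used in the source
# tables (base round() rounds half to even: round(81.25, 1) == 81.2)
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

small_legend <- function(k = 2) {
  data.frame(code = seq_len(k), name = letters[seq_len(k)],
             stringsAsFactors = FALSE)
}

tiny_scene_spec <- function(..., seed = 11L)
  scene_spec(width = 50, height = 50, seed = seed, ...)
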