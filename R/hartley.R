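## Upper 5% points of Hartley's F_max distribution (ratio of the largest
## to the smallest of k independent sample variances, each on df degrees
## of freedom), from the published tables. The k = 2 column is exactly
## qf(0.975, df, df) since F_max = max(F, 1/F) with F ~ F(df, df).

hartley_df <- c(2:10, 12, 15, 20, 30, 60)
hartley_k <- 2:12

hartley_table_05 <- matrix(c(
  ## k =  2      3      4      5      6      7      8      9     10     11     12
        39.0,  87.5, 142,   202,   266,   333,   403,   475,   550,   626,   704,
        15.4,  27.8,  39.2,  50.7,  62.0,  72.9,  83.5,  93.9, 104,   114,   124,
         9.60, 15.5,  20.6,  25.2,  29.5,  33.6,  37.5,  41.1,  44.6,  48.0,  51.4,
         7.15, 10.8,  13.7,  16.3,  18.7,  20.8,  22.9,  24.7,  26.5,  28.2,  29.9,
         5.82,  8.38, 10.4,  12.1,  13.7,  15.0,  16.3,  17.5,  18.6,  19.7,  20.7,
         4.99,  6.94,  8.44,  9.70, 10.8,  11.8,  12.7,  13.5,  14.3,  15.1,  15.8,
         4.43,  6.00,  7.18,  8.12,  9.03,  9.78, 10.5,  11.1,  11.7,  12.2,  12.7,
         4.03,  5.34,  6.31,  7.11,  7.80,  8.41,  8.95,  9.45,  9.91, 10.3,  10.7,
         3.72,  4.85,  5.67,  6.34,  6.92,  7.42,  7.87,  8.28,  8.66,  9.01,  9.34,
         3.28,  4.16,  4.79,  5.30,  5.72,  6.09,  6.42,  6.72,  7.00,  7.25,  7.48,
         2.86,  3.54,  4.01,  4.37,  4.68,  4.95,  5.19,  5.40,  5.59,  5.77,  5.93,
         2.46,  2.95,  3.29,  3.54,  3.76,  3.94,  4.10,  4.24,  4.37,  4.49,  4.59,
         2.07,  2.40,  2.61,  2.78,  2.91,  3.02,  3.12,  3.21,  3.29,  3.36,  3.39,
         1.67,  1.85,  1.96,  2.04,  2.11,  2.17,  2.22,  2.26,  2.30,  2.33,  2.36
), nrow = length(hartley_df), ncol = length(hartley_k), byrow = TRUE,
  dimnames = list(df = hartley_df, k = hartley_k))

## Tabulated / interpolated critical value, or NA when out of range.
## Untabulated df are interpolated linearly in 1/df (the convention for
## F-type tables).
hartley_critical <- function(k, df, alpha = 0.05) {
  if (!isTRUE(all.equal(alpha, 0.05))) return(NA_real_)
  if (!(k %in% hartley_k)) return(NA_real_)
  if (df < min(hartley_df) || df > max(hartley_df)) return(NA_real_)
  col <- hartley_table_05[, as.character(k)]
  if (df %in% hartley_df) return(unname(col[as.character(df)]))
  lo <- max(hartley_df[hartley_df < df])
  hi <- min(hartley_df[hartley_df > df])
  w <- (1 / df - 1 / lo) / (1 / hi - 1 / lo)
  unname(col[as.character(lo)] * (1 - w) + col[as.character(hi)] * w)
}

## Seeded Monte-Carlo estimate of the F_max null quantile under the
## normal equal-variance null; fallback for out-of-table (k, df, alpha).
hartley_critical_mc <- function(k, df, alpha = 0.05, n_rep = 1e5, seed = 1L) {
  with_seed(seed, {
    v <- matrix(stats::rchisq(n_rep * k, df) / df, ncol = k)
    fmax <- apply(v, 1, max) / apply(v, 1, min)
    unname(stats::quantile(fmax, 1 - alpha))
  })
}
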