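# Small, fast simulation specs used across tests.

# noiseless, flat-background, well-separated field
clean_spec <- function(seed = 1, size = 256L, ...) {
  args <- list(field_size_px = c(size, size), seed = seed,
               noise_poisson_gain = 0, noise_read_sd = 0,
               background_gradient = c(0, 0),
               condensate_min_gap_um = 0.5)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_spec, args)
}

# one nucleus, exact condensate count
forced_spec <- function(n_condensates, seed = 1, size = 128L, ...) {
  clean_spec(seed = seed, size = size,
             nucleus_density = 1e4 / (size * 0.173)^2,  # exactly one nucleus
             nucleus_radius_um = 4,
             condensates_per_nucleus = n_condensates,
             condensate_dispersion = 0, ...)
}

# records data frame from a bare vector of areas (all accepted)
records_from_areas <- function(areas) {
  data.frame(area_um2 = areas, accepted = rep(TRUE, length(areas)))
}

# --- independent oracles ----------------------------------------------------

reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * n
  i <- ((i - 1L) %% p + p) %% p
  ifelse(i < n, i + 1L, p - i)
}

# naive grayscale opening by a ball structuring element, double loop
naive_ball_open <- function(img, radius) {
  r <- ceiling(radius)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- offs$dr^2 + offs$dc^2 <= radius^2
  offs <- offs[keep, ]
  h <- sqrt(radius^2 - offs$dr^2 - offs$dc^2)
  nr <- nrow(img); nc <- ncol(img)
  ero <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rr <- reflect_index(i + offs$dr, nr); cc <- reflect_index(j + offs$dc, nc)
    ero[i, j] <- min(img[cbind(rr, cc)] - h)
  }
  dil <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rr <- reflect_index(i - offs$dr, nr); cc <- reflect_index(j - offs$dc, nc)
    dil[i, j] <- max(ero[cbind(rr, cc)] + h)
  }
  dil
}

# naive windowed population variance at a single pixel
naive_window_variance <- function(img, i, j, radius) {
  rr <- reflect_index(i + (-radius:radius), nrow(img))
  cc <- reflect_index(j + (-radius:radius), ncol(img))
  vals <- img[rr, cc]
  mean(vals^2) - mean(vals)^2
}

# direct evaluation of the Holm-Sidak step-down formula
oracle_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# all consecutive-duplicate-free sequences over {A,B,C} of length n
all_entry_sequences <- function(n) {
  arms <- c("A", "B", "C")
  seqs <- as.list(arms)
  for (k in seq_len(n - 1)) {
    seqs <- unlist(lapply(seqs, function(s) {
      lapply(setdiff(arms, s[length(s)]), function(a) c(s, a))
    }), recursive = FALSE)
  }
  seqs
}

# alternation score via the closed form: with no consecutive duplicates a
# triplet is distinct iff its first and third entries differ
oracle_sar <- function(s) {
  n <- length(s)
  sum(s[1:(n - 2)] != s[3:n]) / (n - 2) * 100
}
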