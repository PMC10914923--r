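# Independent oracles, deliberately written long-hand and kept free of any
# package internals, so tests compare two separate routes to each quantity.

# Straight-line reimplementation of the two significance criteria on raw
# sites x replicates matrices (NA = missing cell).
oracle_call_sites <- function(sample_mat, control_mat, min_replicates = 3,
                              eps = 1e-9) {
  n_sites <- nrow(sample_mat)
  out <- data.frame(site = seq_len(n_sites), evaluable = FALSE,
                    raw_mean = NA_real_, control_mean = NA_real_,
                    corrected_mean = NA_real_, corrected_sd = NA_real_,
                    criterion1 = NA, criterion2 = NA, significant = NA)
  for (i in seq_len(n_sites)) {
    xs <- sample_mat[i, ]; xs <- xs[!is.na(xs)]
    xc <- control_mat[i, ]; xc <- xc[!is.na(xc)]
    if (length(xs) < min_replicates || length(xc) < 1) next
    cm <- sum(xc) / length(xc)
    rm_ <- sum(xs) / length(xs)
    corr <- xs - cm
    cmean <- sum(corr) / length(corr)
    csd <- sqrt(sum((corr - cmean)^2) / (length(corr) - 1))
    c1 <- (cmean - 3 * csd) > 0
    c2 <- if (cm < eps) rm_ > 0 else rm_ >= 2 * cm
    out$evaluable[i] <- TRUE
    out$raw_mean[i] <- rm_; out$control_mean[i] <- cm
    out$corrected_mean[i] <- cmean; out$corrected_sd[i] <- csd
    out$criterion1[i] <- c1; out$criterion2[i] <- c2
    out$significant[i] <- c1 && c2
  }
  out
}

# Wrap a raw values matrix as an editing_table the package accepts.
make_editing_table <- function(values, group, edit_mode = "A_to_G",
                               ref_base = if (edit_mode == "A_to_G") "A" else "C") {
  sites <- data.frame(ref_position = seq_len(nrow(values)),
                      ref_base = rep(ref_base, nrow(values)))
  structure(list(edit_mode = edit_mode, group = group, sites = sites,
                 replicate_ids = paste0("rep", seq_len(ncol(values))),
                 values = values),
            class = "editing_table")
}

random_editing_tables <- function(n_sites, n_reps, p_missing = 0.1) {
  rand <- function() {
    m <- matrix(stats::runif(n_sites * n_reps), n_sites, n_reps)
    m[stats::runif(length(m)) < p_missing] <- NA
    m
  }
  list(sample = rand(), control = rand() * 0.2)
}

# Gotoh global alignment with affine gaps (open + k*extend for a length-k
# gap), IUPAC containment scoring; returns the call->reference map.
oracle_align_map <- function(query, ref, match = 2, mismatch = -2,
                             gap_open = 5, gap_ext = 1) {
  q <- strsplit(toupper(query), "")[[1]]
  r <- strsplit(toupper(ref), "")[[1]]
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  sc <- function(a, b)
    if (length(intersect(sets[[a]], sets[[b]]))) match else mismatch
  n <- length(q); m <- length(r)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M   # X: gap in ref, Y: gap in query
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + (i - 1) * gap_ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + (j - 1) * gap_ext)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
      sc(q[i - 1], r[j - 1])
    X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
    Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
  }
  # traceback (prefer diagonal on ties)
  map <- NULL
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1) {
      map <- rbind(c(call_index = i - 2L, ref_position = j - 1L), map)
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      from_m <- abs(X[i, j] - (M[i - 1, j] - gap_open - gap_ext)) < 1e-6
      state <- if (from_m) 1 else 2
      i <- i - 1
    } else {
      from_m <- abs(Y[i, j] - (M[i, j - 1] - gap_open - gap_ext)) < 1e-6
      state <- if (from_m) 1 else 3
      j <- j - 1
    }
  }
  as.data.frame(map)
}

digested_lane <- function(lengths, quantities) {
  structure(data.frame(lane_id = "L1", treatment = "digested",
                       length_nt = lengths, quantity = quantities),
            class = c("band_table", "data.frame"))
}

# Welch t computed from the textbook formulas.
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
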