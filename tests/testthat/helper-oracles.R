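# Independent oracles and generators used across test files.

# Closed-form evoked kernel, written out independently of vep_kernel():
# difference of two unit-peak gamma pulses, renormalized to unit maximum.
kernel_closed_form <- function(t, tp = 0.10, p1 = 8, tu = 0.22, p2 = 12,
                               w = 0.35) {
  g <- function(x, peak, p) ifelse(x > 0, (x / peak)^p * exp(-p * (x / peak - 1)), 0)
  raw <- function(x) g(x, tp, p1) - w * g(x, tu, p2)
  peak_t <- stats::optimize(raw, c(0, tu), maximum = TRUE)$maximum
  raw(t) / raw(peak_t)
}

# build a differential_activity object directly from a numeric series
make_da <- function(d, eye = "OS", times = NULL, subject = "T") {
  if (is.null(times)) times <- seq(0, by = 0.002, length.out = length(d))
  structure(list(subject_id = subject, eye = eye, times = times, d = d),
            class = "differential_activity")
}

# textbook Pearson correlation, spelled out
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# hand-computed paired t statistic
paired_t_oracle <- function(a, b) {
  d <- a - b
  mean(d) / (sd(d) / sqrt(length(d)))
}

# random Mendelian-consistent trio over n_var variants: draw parental
# genotypes, then transmitted alleles, so the child is consistent by
# construction; returns the trio table plus the true transmitted counts.
random_trio <- function(n_var) {
  gts <- c("WT", "Het", "Hom")
  draw_parent <- function() sample(gts, n_var, replace = TRUE,
                                   prob = c(0.5, 0.35, 0.15))
  transmit <- function(g) vapply(g, function(x)
    switch(x, WT = 0L, Hom = 1L, Het = sample(0:1, 1)), integer(1))
  fa <- draw_parent(); mo <- draw_parent()
  tf <- transmit(fa); tm <- transmit(mo)
  child <- c("WT", "Het", "Hom")[tf + tm + 1L]
  data.frame(variant = paste0("v", seq_len(n_var)),
             proband = child, father = fa, mother = mo,
             true_paternal = tf, true_maternal = tm,
             stringsAsFactors = FALSE)
}

# exhaustive allele-assignment phase oracle: enumerate every orientation of
# the proband's Het variants, keep those compatible with what each parent
# can transmit, and call a variant resolved when all surviving assignments
# agree on its side.
brute_force_phase <- function(trios) {
  can_transmit <- function(g, a) switch(g, WT = a == 0, Hom = a == 1,
                                        Het = TRUE)
  carried <- trios[trios$proband != "WT", , drop = FALSE]
  het <- which(carried$proband == "Het")
  n_h <- length(het)
  pat_sets <- list(); mat_sets <- list()
  for (mask in 0:(2^n_h - 1)) {
    pat_cnt <- ifelse(carried$proband == "Hom", 1L, 0L)
    mat_cnt <- ifelse(carried$proband == "Hom", 1L, 0L)
    if (n_h > 0) {
      to_pat <- het[bitwAnd(mask, 2^(seq_len(n_h) - 1)) > 0]
      pat_cnt[to_pat] <- 1L
      mat_cnt[setdiff(het, to_pat)] <- 1L
    }
    ok <- all(mapply(can_transmit, carried$father, pat_cnt)) &&
      all(mapply(can_transmit, carried$mother, mat_cnt))
    # non-carried variants must also be explainable (0 transmissible)
    rest <- trios[trios$proband == "WT", , drop = FALSE]
    ok <- ok && all(vapply(rest$father, can_transmit, logical(1), a = 0)) &&
      all(vapply(rest$mother, can_transmit, logical(1), a = 0))
    if (ok) {
      pat_sets[[length(pat_sets) + 1]] <- carried$variant[pat_cnt == 1L]
      mat_sets[[length(mat_sets) + 1]] <- carried$variant[mat_cnt == 1L]
    }
  }
  if (length(pat_sets) == 0) return(NULL)     # Mendelian-inconsistent
  always_in <- function(v, sets) all(vapply(sets, function(s) v %in% s,
                                            logical(1)))
  pat <- mat <- amb <- character(0)
  for (v in carried$variant) {
    in_pat <- always_in(v, pat_sets); in_mat <- always_in(v, mat_sets)
    if (in_pat && in_mat) { pat <- c(pat, v); mat <- c(mat, v) }
    else if (in_pat) pat <- c(pat, v)
    else if (in_mat) mat <- c(mat, v)
    else amb <- c(amb, v)
  }
  list(paternal = sort(pat), maternal = sort(mat), ambiguous = sort(amb))
}

# random STR pedigree with a known transmission pattern
random_str_pedigree <- function(n_markers = 9, pool = 4L) {
  markers <- paste0("M", seq_len(n_markers))
  alleles <- function() matrix(sample(100 + 2 * seq_len(pool), 2 * n_markers,
                                      replace = TRUE), 2, n_markers)
  tr <- function() c(paternal = sample(1:2, 1), maternal = sample(1:2, 1))
  trans <- list(sib1 = tr(), sib2 = tr())
  cfg <- str_pedigree_config(markers, alleles(), alleles(), trans)
  list(cfg = cfg, str = simulate_str_pedigree(cfg), trans = trans)
}
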