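# shared fixtures and independent oracles, all built in code

marker_labels <- c("FA 2-OH C16:0_N", "FA C18:0_N", "TUDCA_N",
                   "PE ae C36:4_N", "PE aa C38:6_N", "LysoPC a C20:4_P")

# a small valid raw table: n samples (half cases), p features
tiny_table <- function(n = 6, p = 4, seed = 42) {
  set.seed(seed)
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:n),
    group = rep(c("case", "control"), length.out = n),
    cohort = "c1", batch = "b1", timepoint = "<=6h",
    stringsAsFactors = FALSE
  )
  features <- data.frame(
    feature_id = sprintf("f%02d", 1:p),
    mz = round(runif(p, 60, 1100), 4),
    esi_mode = rep(c("NEG", "POS"), length.out = p),
    annotation = NA_character_,
    stringsAsFactors = FALSE
  )
  feature_table(samples, features, matrix(rexp(n * p, 0.01), n, p))
}

# an autoscaled-state table with one feature ("spike") shifted by d in cases
spiked_table <- function(n_case = 40, n_ctrl = 40, n_noise = 50, d = 3,
                         seed = 1) {
  set.seed(seed)
  n <- n_case + n_ctrl
  p <- n_noise + 1
  x <- matrix(rnorm(n * p), n, p)
  x[seq_len(n_case), 1] <- x[seq_len(n_case), 1] + d
  samples <- data.frame(
    sample_id = sprintf("s%03d", 1:n),
    group = c(rep("case", n_case), rep("control", n_ctrl)),
    stringsAsFactors = FALSE
  )
  features <- data.frame(
    feature_id = c("spike", sprintf("noise%03d", seq_len(n_noise))),
    mz = round(seq(100, 900, length.out = p), 4),
    esi_mode = "NEG",
    stringsAsFactors = FALSE
  )
  feature_table(samples, features, x, transform_state = "autoscaled")
}

# brute-force pairwise AUC oracle: P(case > control) + 0.5 P(tie)
bf_auc <- function(scores, labels) {
  cs <- scores[labels == 1]
  ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# independent sequential minimum-error assignment oracle for the matcher:
# repeatedly pick the globally smallest-|error| in-threshold pair among
# unassigned features and unclaimed (compound, mode) slots
bf_match <- function(features, library, threshold) {
  rec <- library$records[!library$records$is_drug_or_nonhuman, , drop = FALSE]
  cand <- expand.grid(f = seq_len(nrow(features)), c = seq_len(nrow(rec)))
  cand$err <- features$mz[cand$f] -
    expected_mz(rec$monoisotopic_mass[cand$c], features$esi_mode[cand$f])
  cand <- cand[abs(cand$err) <= threshold, , drop = FALSE]
  cand <- cand[order(abs(cand$err), features$mz[cand$f],
                     rec$name[cand$c]), , drop = FALSE]
  out <- NULL
  while (nrow(cand) > 0) {
    top <- cand[1, ]
    out <- rbind(out, data.frame(
      feature_id = features$feature_id[top$f],
      compound_name = rec$name[top$c],
      mass_error = top$err, stringsAsFactors = FALSE))
    key_mode <- features$esi_mode[top$f]
    keep <- cand$f != top$f &
      !(cand$c == top$c & features$esi_mode[cand$f] == key_mode)
    cand <- cand[keep, , drop = FALSE]
  }
  out
}

# small synthetic config used where the full 1400-noise tables are overkill
fast_config <- function(seed, n_noise = 60, ...) {
  synthetic_config(seed = seed, n_noise_features_per_mode = n_noise, ...)
}

# stack two cohorts that share all feature ids into one table
stack_cohorts <- function(a, b) {
  shared <- intersect(a$features$feature_id, b$features$feature_id)
  ia <- match(shared, a$features$feature_id)
  feature_table(rbind(a$samples, b$samples),
                a$features[ia, , drop = FALSE],
                rbind(a$abundances[, shared, drop = FALSE],
                      b$abundances[, shared, drop = FALSE]),
                a$transform_state)
}
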