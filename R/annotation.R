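#' @rdname expected_mz
#' @format NULL
#' @export
proton_mass <- 1.007276

#' Expected m/z of a neutral compound under single protonation
#'
#' Singly charged adducts only: deprotonation \eqn{[M-H]^-} in NEG mode,
#' protonation \eqn{[M+H]^+} in POS mode, so the observed m/z is the neutral
#' monoisotopic mass minus/plus one proton (1.007276 Da).
#'
#' @param M neutral monoisotopic mass (Da).
#' @param mode `"NEG"` or `"POS"`.
#' @return expected m/z (Da).
#' @examples
#' expected_mz(272.235, "NEG")  # FA 2-OH C16:0 -> 271.2277
#' expected_mz(543.3325, "POS") # LysoPC a C20:4 -> 544.3398
#' @export
expected_mz <- function(M, mode) {
  if (!all(mode %in% c("NEG", "POS"))) {
    stop("unknown ESI mode: ", paste(setdiff(mode, c("NEG", "POS")),
                                     collapse = ", "), call. = FALSE)
  }
  n <- max(length(M), length(mode))
  M <- rep_len(M, n)
  mode <- rep_len(mode, n)
  if (any(mode == "NEG" & M < proton_mass)) {
    stop("neutral mass below one proton cannot deprotonate", call. = FALSE)
  }
  ifelse(mode == "NEG", M - proton_mass, M + proton_mass)
}

# Name_N / Name_P labels, suffix per ESI mode
.annotation_label <- function(name, mode) {
  paste0(name, "_", ifelse(mode == "NEG", "N", "P"))
}

#' Match m/z features to library compounds by monoisotopic mass
#'
#' Stepwise best matching: every (feature, compound) pair within `threshold`
#' Da of the compound's mode-adjusted expected m/z is a candidate; candidates
#' are taken in ascending |mass error| (ties broken by ascending m/z, then
#' compound name), the globally smallest-error candidate becomes a primary
#' annotation and removes its feature and its (compound, mode) slot from
#' further primary consideration; remaining in-threshold candidates are
#' flagged as secondary matches (the "separate tab"); features with no
#' candidate are dropped from the annotated output (data reduction).
#'
#' @param features data.frame with `feature_id`, `mz`, `esi_mode`, or a
#'   [feature_table()].
#' @param library a [compound_library()]; drug / non-human records are
#'   excluded from the matching set.
#' @param threshold matching threshold in Da (default 0.01; 0.05 is the
#'   looser conventional choice).
#' @return an `annotation_result`: list with data.frames `primary` and
#'   `flagged` (columns `feature_id`, `compound_name`, `esi_mode`, `mz`,
#'   `expected_mz`, `mass_error`, `label`, `rank`), plus `threshold`,
#'   `n_input_features`, `n_annotated`.
#' @export
match_features <- function(features, library, threshold = 0.01) {
  if (inherits(features, "feature_table")) features <- features$features
  stopifnot(inherits(library, "compound_library"))
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("matching threshold must be positive", call. = FALSE)
  }
  rec <- matching_records(library)
  if (nrow(rec) == 0) stop("empty compound library", call. = FALSE)
  n_input <- nrow(features)

  cand <- list()
  for (mode in c("NEG", "POS")) {
    fi <- which(features$esi_mode == mode)
    if (!length(fi)) next
    exp_mz <- expected_mz(rec$monoisotopic_mass, mode)
    err <- outer(features$mz[fi], exp_mz, "-")  # feature x compound
    hit <- which(abs(err) <= threshold, arr.ind = TRUE)
    if (!nrow(hit)) next
    cand[[mode]] <- data.frame(
      feature_id = features$feature_id[fi[hit[, 1]]],
      compound_name = rec$name[hit[, 2]],
      esi_mode = mode,
      mz = features$mz[fi[hit[, 1]]],
      expected_mz = exp_mz[hit[, 2]],
      mass_error = err[cbind(hit[, 1], hit[, 2])],
      stringsAsFactors = FALSE
    )
  }
  cand <- do.call(rbind, cand)
  empty <- data.frame(
    feature_id = character(), compound_name = character(),
    esi_mode = character(), mz = numeric(), expected_mz = numeric(),
    mass_error = numeric(), label = character(), rank = character(),
    stringsAsFactors = FALSE
  )
  if (is.null(cand) || nrow(cand) == 0) {
    return(structure(list(primary = empty, flagged = empty,
                          threshold = threshold,
                          n_input_features = n_input, n_annotated = 0L),
                     class = "annotation_result"))
  }
  ord <- order(abs(cand$mass_error), cand$mz, cand$compound_name)
  cand <- cand[ord, , drop = FALSE]
  used_feature <- character()
  used_compound <- character()  # keyed compound|mode
  rank <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ckey <- paste(cand$compound_name[i], cand$esi_mode[i], sep = "|")
    if (!(cand$feature_id[i] %in% used_feature) &&
        !(ckey %in% used_compound)) {
      rank[i] <- "primary"
      used_feature <- c(used_feature, cand$feature_id[i])
      used_compound <- c(used_compound, ckey)
    } else {
      rank[i] <- "secondary"
    }
  }
  cand$label <- .annotation_label(cand$compound_name, cand$esi_mode)
  cand$rank <- rank
  primary <- cand[rank == "primary", , drop = FALSE]
  flagged <- cand[rank == "secondary", , drop = FALSE]
  rownames(primary) <- rownames(flagged) <- NULL
  structure(list(primary = primary, flagged = flagged,
                 threshold = threshold, n_input_features = n_input,
                 n_annotated = nrow(primary)),
            class = "annotation_result")
}

#' @method print annotation_result
#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf(
    "<annotation_result> %d / %d features annotated (threshold %.3g Da), %d flagged secondaries\n",
    x$n_annotated, x$n_input_features, x$threshold, nrow(x$flagged)))
  invisible(x)
}

#' Annotate a feature table and reduce it to named metabolites
#'
#' Runs [match_features()] and keeps only the primary-annotated features,
#' renaming each `feature_id` to its `Name_N` / `Name_P` label; abundance
#' columns are preserved. Unannotatable features are dropped, the initial
#' data-reduction step of the workflow.
#'
#' @inheritParams match_features
#' @param table a [feature_table()].
#' @return the reduced, annotated [feature_table()] (same transform state).
#' @export
annotate_table <- function(table, library, threshold = 0.01) {
  stopifnot(inherits(table, "feature_table"))
  res <- match_features(table$features, library, threshold)
  if (res$n_annotated == 0) {
    warning("no features matched the library within ", threshold,
            " Da; returning an empty annotated table", call. = FALSE)
  }
  idx <- match(res$primary$feature_id, table$features$feature_id)
  features <- data.frame(
    feature_id = res$primary$label,
    mz = table$features$mz[idx],
    esi_mode = res$primary$esi_mode,
    annotation = res$primary$compound_name,
    stringsAsFactors = FALSE
  )
  feature_table(table$samples, features,
                table$abundances[, idx, drop = FALSE],
                table$transform_state)
}

#' Restrict a panel to the analytes present in another cohort's table
#'
#' Keeps, in their original order, only the panel labels that exist among
#' the features of an annotated table from another cohort — the step that
#' turns a 10-analyte discovery panel into the 6- or 8-analyte panel shared
#' by both cohorts when batches yield discrepant feature sets.
#'
#' @param panel a [panel_definition()] with `Name_Mode` labels.
#' @param other an annotated [feature_table()].
#' @return a [panel_definition()] containing the common labels; dropped
#'   labels are messaged, an empty result warns.
#' @export
intersect_common <- function(panel, other) {
  stopifnot(inherits(panel, "panel_definition"),
            inherits(other, "feature_table"))
  keep <- panel$labels %in% other$features$feature_id
  dropped <- panel$labels[!keep]
  if (length(dropped)) {
    message("dropping ", length(dropped), " label(s) absent from the other ",
            "cohort: ", paste(dropped, collapse = ", "))
  }
  if (!any(keep)) {
    warning("no panel labels present in the other cohort", call. = FALSE)
  }
  panel_definition(panel$labels[keep], method = panel$method, k = panel$k)
}
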