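#' Construct an untargeted LC-MS feature table
#'
#' The central container of the pipeline: a samples-by-features matrix of
#' relative abundances plus sample metadata (group, cohort, batch, timepoint)
#' and feature metadata (m/z, ESI mode, optional annotation label).
#' Internally samples are rows and features are columns, the statistics
#' convention; on disk the canonical layout is transposed (XCMS-style,
#' features as rows) and [read_feature_table()] auto-detects either.
#'
#' @param samples data.frame with columns `sample_id` (unique), `group`
#'   (non-empty, conventionally `"case"`/`"control"`), and optionally
#'   `cohort`, `batch`, `timepoint` (defaulted to `""`).
#' @param features data.frame with columns `feature_id` (unique), `mz`
#'   (within the 50-1200 instrument scan range), `esi_mode` (`"NEG"` or
#'   `"POS"`), and optionally `annotation`.
#' @param abundances numeric matrix, `nrow(samples)` x `nrow(features)`,
#'   non-negative when `transform_state = "raw"`.
#' @param transform_state one of `"raw"`, `"glog"`, `"autoscaled"`.
#'   Transitions only ever run raw -> glog -> autoscaled.
#' @return an object of class `feature_table`.
#' @seealso [read_feature_table()], [glog_transform()], [annotate_table()]
#' @export
feature_table <- function(samples, features, abundances,
                          transform_state = "raw") {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group")) {
    if (!col %in% names(samples)) {
      stop("samples must carry a '", col, "' column", call. = FALSE)
    }
  }
  for (col in c("cohort", "batch", "timepoint")) {
    if (!col %in% names(samples)) samples[[col]] <- ""
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in feature table", call. = FALSE)
  }
  if (any(is.na(samples$group) | samples$group == "")) {
    stop("every sample needs a non-empty group label", call. = FALSE)
  }
  for (col in c("feature_id", "mz", "esi_mode")) {
    if (!col %in% names(features)) {
      stop("features must carry a '", col, "' column", call. = FALSE)
    }
  }
  if (!"annotation" %in% names(features)) features$annotation <- NA_character_
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id in feature table", call. = FALSE)
  }
  features$mz <- as.numeric(features$mz)
  if (any(is.na(features$mz)) ||
      any(features$mz < 50 - 1e-9 | features$mz > 1200 + 1e-9)) {
    stop("feature mz values must lie in the 50-1200 scan range", call. = FALSE)
  }
  if (!all(features$esi_mode %in% c("NEG", "POS"))) {
    stop("esi_mode must be 'NEG' or 'POS'", call. = FALSE)
  }
  transform_state <- match.arg(transform_state,
                               c("raw", "glog", "autoscaled"))
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  if (nrow(abundances) != nrow(samples) ||
      ncol(abundances) != nrow(features)) {
    stop("abundance matrix must be n_samples x n_features", call. = FALSE)
  }
  if (anyNA(abundances)) {
    stop("abundance matrix contains missing values; encode non-detects as 0",
         call. = FALSE)
  }
  if (transform_state == "raw" && any(abundances < 0)) {
    stop("raw abundances must be non-negative", call. = FALSE)
  }
  rownames(abundances) <- samples$sample_id
  colnames(abundances) <- features$feature_id
  structure(
    list(samples = samples, features = features, abundances = abundances,
         transform_state = transform_state),
    class = "feature_table"
  )
}

#' @method print feature_table
#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d features [%s]\n",
    nrow(x$samples), nrow(x$features), x$transform_state))
  grp <- table(x$samples$group)
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  modes <- table(x$features$esi_mode)
  cat("  modes: ", paste(names(modes), modes, sep = "=", collapse = ", "),
      "\n")
  n_ann <- sum(!is.na(x$features$annotation))
  cat("  annotated features:", n_ann, "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundances)

# metadata rows written above the feature block in the canonical layout
.ft_meta_rows <- c("#group", "#cohort", "#batch", "#timepoint",
                   "#transform_state")

#' Read a feature table from delimited text
#'
#' Accepts two layouts, auto-detected from the header: the canonical
#' transposed layout written by [write_feature_table()] (header starts with
#' `feature_id,mz,esi_mode,annotation`, one row per feature, sample metadata
#' in `#`-prefixed rows), or a samples-as-rows layout whose feature columns
#' are named `"<mz>@<MODE>"` (e.g. `"271.2277@NEG"`) after the sample
#' metadata columns.
#'
#' @param path file path to a CSV/TSV file.
#' @param sep field separator, `","` by default.
#' @return a validated [feature_table()] (with the stored `transform_state`,
#'   `"raw"` if none is recorded).
#' @export
read_feature_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  header <- names(raw)
  if (identical(header[1], "feature_id")) {
    return(.read_transposed(raw))
  }
  if (identical(header[1], "sample_id")) {
    return(.read_samples_rows(raw))
  }
  stop("unrecognized feature-table layout: header must start with ",
       "'feature_id' (transposed) or 'sample_id' (samples as rows)",
       call. = FALSE)
}

.read_transposed <- function(raw) {
  for (col in c("mz", "esi_mode")) {
    if (!col %in% names(raw)) {
      stop("feature-table format error: missing '", col, "' column",
           call. = FALSE)
    }
  }
  if (!"annotation" %in% names(raw)) raw$annotation <- NA_character_
  meta_idx <- which(raw$feature_id %in% .ft_meta_rows)
  sample_cols <- setdiff(names(raw),
                         c("feature_id", "mz", "esi_mode", "annotation"))
  if (length(sample_cols) == 0) {
    stop("feature-table format error: no sample columns found",
         call. = FALSE)
  }
  samples <- data.frame(sample_id = sample_cols, group = "",
                        stringsAsFactors = FALSE)
  transform_state <- "raw"
  for (i in meta_idx) {
    key <- sub("^#", "", raw$feature_id[i])
    vals <- as.character(unlist(raw[i, sample_cols]))
    if (key == "transform_state") transform_state <- vals[1]
    else samples[[key]] <- vals
  }
  feat <- raw[setdiff(seq_len(nrow(raw)), meta_idx), , drop = FALSE]
  features <- data.frame(
    feature_id = feat$feature_id,
    mz = as.numeric(feat$mz),
    esi_mode = feat$esi_mode,
    annotation = ifelse(is.na(feat$annotation) | feat$annotation == "",
                        NA_character_, feat$annotation),
    stringsAsFactors = FALSE
  )
  ab <- matrix(as.numeric(as.matrix(feat[, sample_cols, drop = FALSE])),
               nrow = nrow(feat), ncol = length(sample_cols))
  feature_table(samples, features, t(ab), transform_state)
}

.read_samples_rows <- function(raw) {
  meta_cols <- intersect(c("sample_id", "group", "cohort", "batch",
                           "timepoint"), names(raw))
  feat_cols <- setdiff(names(raw), meta_cols)
  is_tok <- grepl("^[0-9.]+@(NEG|POS)$", feat_cols)
  if (!any(is_tok)) {
    stop("feature-table format error: missing 'mz' information - no ",
         "'<mz>@<MODE>' feature columns found", call. = FALSE)
  }
  if (!all(is_tok)) {
    stop("feature-table format error: unparseable feature columns: ",
         paste(utils::head(feat_cols[!is_tok], 3), collapse = ", "),
         call. = FALSE)
  }
  features <- data.frame(
    feature_id = feat_cols,
    mz = as.numeric(sub("@.*$", "", feat_cols)),
    esi_mode = sub("^.*@", "", feat_cols),
    annotation = NA_character_,
    stringsAsFactors = FALSE
  )
  ab <- as.matrix(raw[, feat_cols, drop = FALSE])
  feature_table(raw[, meta_cols, drop = FALSE], features, ab)
}

#' Write a feature table in the canonical transposed layout
#'
#' One row per feature (`feature_id`, `mz`, `esi_mode`, `annotation`, then
#' one column per sample); sample metadata travel in `#group` / `#cohort` /
#' `#batch` / `#timepoint` / `#transform_state` rows above the feature
#' block. Abundances are serialized with full precision so that
#' `read_feature_table(write_feature_table(x))` is the identity.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$features) == 0) {
    warning("writing a feature table with no features", call. = FALSE)
  }
  n_s <- nrow(table$samples)
  meta <- data.frame(
    feature_id = .ft_meta_rows,
    mz = NA_real_, esi_mode = "", annotation = "",
    stringsAsFactors = FALSE
  )
  meta_vals <- rbind(table$samples$group, table$samples$cohort,
                     table$samples$batch, table$samples$timepoint,
                     rep(table$transform_state, n_s))
  body <- data.frame(
    feature_id = table$features$feature_id,
    mz = table$features$mz,
    esi_mode = table$features$esi_mode,
    annotation = ifelse(is.na(table$features$annotation), "",
                        table$features$annotation),
    stringsAsFactors = FALSE
  )
  body_vals <- t(table$abundances)
  all_vals <- rbind(meta_vals,
                    matrix(format(body_vals, digits = 15, trim = TRUE),
                           nrow = nrow(body), ncol = n_s))
  out <- cbind(rbind(meta, body), as.data.frame(all_vals,
                                                stringsAsFactors = FALSE))
  names(out) <- c("feature_id", "mz", "esi_mode", "annotation",
                  table$samples$sample_id)
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write feature table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write an annotation result as a paired-sheet workbook
#'
#' Mirrors the two-tab spreadsheet of the annotation step: sheet 1 holds the
#' primary annotated features (best-matched name, HMDB/PubChem IDs,
#' monoisotopic mass, mass error), sheet 2 the flagged secondary matches.
#' Sheets are emitted as a pair of delimited files,
#' `<base>_primary.csv` and `<base>_flagged.csv`.
#'
#' @param result an `annotation_result` from [match_features()].
#' @param path base output path; a `.csv` extension is stripped before the
#'   `_primary` / `_flagged` suffixes are added.
#' @param library optional [compound_library()] used to fill the ID columns;
#'   compounds absent from it get empty ID cells.
#' @return character vector of the two paths written, invisibly.
#' @export
write_annotation_workbook <- function(result, path, library = NULL) {
  stopifnot(inherits(result, "annotation_result"))
  base <- sub("\\.csv$", "", path)
  paths <- paste0(base, c("_primary.csv", "_flagged.csv"))
  decorate <- function(df) {
    df$hmdb_id <- rep("", nrow(df))
    df$pubchem_id <- rep("", nrow(df))
    df$monoisotopic_mass <- rep(NA_real_, nrow(df))
    if (!is.null(library)) {
      idx <- match(df$compound_name, library$records$name)
      hit <- !is.na(idx)
      df$hmdb_id[hit] <- .na_blank(library$records$hmdb_id[idx[hit]])
      df$pubchem_id[hit] <- .na_blank(library$records$pubchem_id[idx[hit]])
      df$monoisotopic_mass[hit] <- library$records$monoisotopic_mass[idx[hit]]
    }
    df
  }
  for (i in 1:2) {
    sheet <- decorate(if (i == 1) result$primary else result$flagged)
    ok <- tryCatch({
      utils::write.csv(sheet, paths[i], row.names = FALSE, na = "")
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write annotation workbook to ", paths[i],
                          ": ", conditionMessage(ok), call. = FALSE)
  }
  invisible(paths)
}

.na_blank <- function(x) ifelse(is.na(x), "", as.character(x))

# group labels as a 0/1 case indicator; errors unless exactly two groups
.case_indicator <- function(table, positive = "case") {
  g <- table$samples$group
  lev <- unique(g)
  if (length(lev) != 2) {
    stop("exactly two sample groups are required, found: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  if (!positive %in% lev) {
    stop("positive class '", positive, "' not among group labels",
         call. = FALSE)
  }
  as.integer(g == positive)
}
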