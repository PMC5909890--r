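# Most-abundant-isotope masses (Da), IUPAC/CODATA values to 6 dp.
# Only monoisotopic matching is needed, so no isotope-pattern modeling.
.isotope_masses <- c(
  C = 12.000000, H = 1.007825, N = 14.003074, O = 15.994915,
  P = 30.973762, S = 31.972071, Na = 22.989770, K = 38.963707,
  Cl = 34.968853, F = 18.998403, Se = 79.916522, Fe = 55.934942
)

#' Monoisotopic mass of an elemental formula
#'
#' Sums most-abundant-isotope masses over the element counts of a Hill-style
#' formula (e.g. `"C18H36O2"`). Deterministic and additive:
#' `monoisotopic_mass("AB")` equals
#' `monoisotopic_mass("A") + monoisotopic_mass("B")` for concatenated
#' formulas.
#'
#' @param formula character vector of elemental formulas over the supported
#'   elements (C, H, N, O, P, S and common hetero atoms).
#' @return numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopic_mass("C18H36O2")   # stearic acid, 284.2715
#' monoisotopic_mass("C26H45NO6S") # tauroursodeoxycholic acid, 499.2968
#' @export
monoisotopic_mass <- function(formula) {
  vapply(as.character(formula), function(f) {
    if (is.na(f) || !nzchar(f)) stop("empty formula", call. = FALSE)
    tokens <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
    if (!nzchar(paste(tokens, collapse = "")) ||
        nchar(paste(tokens, collapse = "")) != nchar(f)) {
      stop("cannot parse formula: ", f, call. = FALSE)
    }
    total <- 0
    for (tok in tokens) {
      el <- gsub("[0-9]", "", tok)
      n <- suppressWarnings(as.numeric(gsub("[^0-9]", "", tok)))
      if (is.na(n)) n <- 1
      if (!el %in% names(.isotope_masses)) {
        stop("unknown element symbol '", el, "' in formula ", f,
             call. = FALSE)
      }
      total <- total + .isotope_masses[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Construct a compound library
#'
#' A reference set of metabolites carrying monoisotopic masses, the target
#' set for m/z annotation. Records flagged `is_drug_or_nonhuman` are kept
#' but excluded from the default matching set, mirroring the practice of
#' annotating against human metabolome databases with drugs and non-human
#' compounds removed.
#'
#' @param records data.frame with at least `name` and one of `formula` /
#'   `monoisotopic_mass`; optional columns `compound_class`, `hmdb_id`,
#'   `pubchem_id`, `lipidmaps_id`, `is_drug_or_nonhuman`, `expected_mode`.
#' @param source_names character vector naming the upstream databases the
#'   records were drawn from.
#' @param mass_tolerance maximum allowed |computed - stored| disagreement
#'   (Da) when both a formula and a stored mass are present; offending
#'   records are dropped with a warning.
#' @return an object of class `compound_library`.
#' @export
compound_library <- function(records, source_names = character(),
                             mass_tolerance = 0.005) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"name" %in% names(records)) {
    stop("library records need a 'name' column", call. = FALSE)
  }
  if (!"formula" %in% names(records)) records$formula <- NA_character_
  records$formula[which(records$formula == "")] <- NA_character_
  if (!"monoisotopic_mass" %in% names(records)) {
    records$monoisotopic_mass <- NA_real_
  }
  for (col in c("compound_class", "hmdb_id", "pubchem_id", "lipidmaps_id")) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }
  if (!"is_drug_or_nonhuman" %in% names(records)) {
    records$is_drug_or_nonhuman <- FALSE
  }
  records$is_drug_or_nonhuman <- as.logical(records$is_drug_or_nonhuman)
  no_mass <- is.na(records$monoisotopic_mass) & is.na(records$formula)
  if (any(no_mass)) {
    stop("records without formula or monoisotopic_mass: ",
         paste(utils::head(records$name[no_mass], 3), collapse = ", "),
         call. = FALSE)
  }
  need <- is.na(records$monoisotopic_mass)
  if (any(need)) {
    records$monoisotopic_mass[need] <-
      monoisotopic_mass(records$formula[need])
  }
  both <- !is.na(records$formula)
  if (any(both)) {
    delta <- abs(monoisotopic_mass(records$formula[both]) -
                   records$monoisotopic_mass[both])
    bad <- which(both)[delta > mass_tolerance]
    if (length(bad)) {
      warning("dropping ", length(bad), " record(s) whose formula mass ",
              "disagrees with the stored mass by > ", mass_tolerance,
              " Da: ", paste(records$name[bad], collapse = ", "),
              call. = FALSE)
      records <- records[-bad, , drop = FALSE]
    }
  }
  if (any(records$monoisotopic_mass <= 0)) {
    stop("monoisotopic masses must be positive", call. = FALSE)
  }
  if (anyDuplicated(records$name)) {
    stop("library compound names must be unique", call. = FALSE)
  }
  rownames(records) <- NULL
  structure(list(records = records, source_names = source_names),
            class = "compound_library")
}

#' @method print compound_library
#' @export
print.compound_library <- function(x, ...) {
  cat(sprintf("<compound_library> %d records (%d excluded as drug/non-human)\n",
              nrow(x$records), sum(x$records$is_drug_or_nonhuman)))
  if (length(x$source_names)) {
    cat("  sources:", paste(x$source_names, collapse = ", "), "\n")
  }
  invisible(x)
}

# the default matching set: human metabolites only
matching_records <- function(library) {
  library$records[!library$records$is_drug_or_nonhuman, , drop = FALSE]
}

#' Load a compound library from delimited text
#'
#' @param path CSV file with columns `name`, `formula` and/or
#'   `monoisotopic_mass`, and optionally `compound_class`, `hmdb_id`,
#'   `pubchem_id`, `lipidmaps_id`, `is_drug_or_nonhuman`, `expected_mode`.
#' @param source_names passed through to [compound_library()].
#' @return a validated [compound_library()]; records whose formula and
#'   stored mass disagree by more than 0.005 Da are rejected with a warning.
#' @export
load_library <- function(path, source_names = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  compound_library(rec, source_names = source_names)
}

#' The six MS/MS-confirmed marker metabolites
#'
#' The confirmed plasma biomarker panel: two fatty acids (FA 2-OH C16:0,
#' FA C18:0), the bile acid TUDCA, two phosphatidylethanolamines
#' (PE ae C36:4, PE aa C38:6) and LysoPC a C20:4, with their printed
#' monoisotopic masses, database IDs, expected ESI modes, and the direction
#' each moves with TBI (`"down"`/`"up"`) carried as `tbi_direction`.
#'
#' @return a [compound_library()] of six records.
#' @export
builtin_panel_library <- function() {
  rec <- data.frame(
    name = c("FA 2-OH C16:0", "FA C18:0", "TUDCA", "PE ae C36:4",
             "PE aa C38:6", "LysoPC a C20:4"),
    formula = c("C16H32O3", "C18H36O2", "C26H45NO6S", "C41H74NO7P",
                "C43H74NO8P", "C28H50NO7P"),
    monoisotopic_mass = c(272.235, 284.272, 499.2968, 723.5203,
                          763.5152, 543.3325),
    compound_class = c("FA", "FA", "bile acid", "PE", "PE", "LysoPC"),
    hmdb_id = c("HMDB31057", "HMDB00827", "HMDB00874",
                "HMDB11352;HMDB11353", "HMDB08946", "HMDB10395"),
    pubchem_id = c("92836", "5281", "9848818", "52925126", "9546799",
                   "24779476"),
    lipidmaps_id = c("LMFA01050047", "LMFA01010018", "LMST05040015",
                     "LMGP02030093", "LMGP02010095", "LMGP01050048"),
    is_drug_or_nonhuman = FALSE,
    expected_mode = c("NEG", "NEG", "NEG", "NEG", "NEG", "POS"),
    tbi_direction = c("down", "up", "down", "up", "down", "up"),
    stringsAsFactors = FALSE
  )
  compound_library(rec, source_names = "MS/MS-confirmed panel")
}

#' The packaged simulation library
#'
#' The six confirmed marker metabolites of [builtin_panel_library()] plus
#' ~300 synthetic stand-in records (names prefixed `Syn`) spanning
#' 60-1190 Da across common plasma compound classes, including a few
#' drug records that are excluded from matching by default. The synthetic
#' records exist for simulation realism only; no real-database snapshot is
#' shipped.
#'
#' @return a [compound_library()] of ~306 records.
#' @export
default_library <- function() {
  path <- system.file("extdata", "compound_library_synthetic.csv",
                      package = "mzpanel", mustWork = TRUE)
  lib <- load_library(path, source_names = "packaged synthetic library")
  # carry marker directions for the simulator
  panel <- builtin_panel_library()$records
  lib$records$tbi_direction <-
    panel$tbi_direction[match(lib$records$name, panel$name)]
  lib
}
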