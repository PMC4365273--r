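#' @importFrom rlang .data
#' @importFrom stats sd setNames quantile median qchisq pchisq rnorm runif rbeta qbeta uniroot
NULL

STUDY_COLUMNS <- c("ID", "TIME", "AMT", "RATE", "EVID", "DVID", "DV", "MDV",
                   "WT", "AGE", "SEX", "SNP2578", "SNP1154", "SNP634")

SNP_LEVELS <- list(SNP2578 = c("CC", "CA", "AA"),
                   SNP1154 = c("GG", "GA", "AA"),
                   SNP634  = c("GG", "GC", "CC"))

#' Assemble a longitudinal PK study dataset
#'
#' Builds the tidy event-per-row table (NONMEM-style layout) every pipeline
#' stage consumes: dose rows (`EVID = 1`, `AMT` in mg over an infusion of
#' `AMT/RATE` days) and observation rows (`EVID = 0`; `DVID = 1` total drug
#' in mg/L, `DVID = 2` free target in ng/L). Subject-constant covariates are
#' repeated on every row.
#'
#' @param data A data frame with (at least) the columns
#'   `r paste(STUDY_COLUMNS, collapse = ", ")`.
#' @return A validated tibble of class `study_dataset`.
#' @seealso [read_study_csv()], [write_study_csv()], [validate_study_dataset()]
#' @export
study_dataset <- function(data) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(STUDY_COLUMNS, names(data))
  if (length(missing_cols) > 0) {
    stop("Dataset is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[STUDY_COLUMNS]
  class(data) <- c("study_dataset", class(data))
  validate_study_dataset(data)
}

#' Validate a study dataset
#'
#' Checks the structural invariants of the event table: times sorted and
#' non-negative within subject, non-negative dose amounts with positive
#' infusion rates, strictly positive observed concentrations (no
#' below-quantification handling is provided because the design assumes
#' none is needed), valid event/observation codes, positive weight and age,
#' subject-constant covariates, and at least one dose per subject that has
#' observations.
#'
#' @param data A data frame in the [study_dataset()] layout.
#' @return The (invisibly classed) validated tibble; errors name the first
#'   offending row.
#' @export
validate_study_dataset <- function(data) {
  fail <- function(row, msg) {
    stop(sprintf("Invalid dataset at row %d: %s", row, msg), call. = FALSE)
  }
  n <- nrow(data)
  if (n == 0) {
    return(data)
  }
  if (any(bad <- !data$EVID %in% c(0, 1))) fail(which(bad)[1], "EVID must be 0 or 1")
  if (any(bad <- !is.finite(data$TIME) | data$TIME < 0)) {
    fail(which(bad)[1], "TIME must be finite and non-negative")
  }
  dose <- data$EVID == 1
  if (any(bad <- dose & (!is.finite(data$AMT) | data$AMT < 0))) {
    fail(which(bad)[1], "dose AMT must be non-negative")
  }
  if (any(bad <- dose & (!is.finite(data$RATE) | data$RATE <= 0))) {
    fail(which(bad)[1], "dose RATE must be positive (bolus doses are not modelled)")
  }
  obs <- data$EVID == 0 & data$MDV == 0
  if (any(bad <- obs & (!is.finite(data$DV) | data$DV <= 0))) {
    fail(which(bad)[1], "observed DV must be a positive concentration")
  }
  if (any(bad <- data$EVID == 0 & !data$DVID %in% c(1, 2))) {
    fail(which(bad)[1], "observation DVID must be 1 (total drug) or 2 (free target)")
  }
  if (any(bad <- !is.finite(data$WT) | data$WT <= 0)) {
    fail(which(bad)[1], "WT must be positive")
  }
  if (any(bad <- !is.finite(data$AGE) | data$AGE <= 0)) {
    fail(which(bad)[1], "AGE must be positive")
  }
  if (any(bad <- !data$SEX %in% c(0, 1))) {
    fail(which(bad)[1], "SEX must be 0 (female) or 1 (male)")
  }
  for (snp in names(SNP_LEVELS)) {
    if (any(bad <- !data[[snp]] %in% SNP_LEVELS[[snp]])) {
      fail(which(bad)[1], sprintf("%s must be one of %s", snp,
                                  paste(SNP_LEVELS[[snp]], collapse = "/")))
    }
  }
  for (id in unique(data$ID)) {
    rows <- which(data$ID == id)
    tt <- data$TIME[rows]
    if (is.unsorted(tt)) {
      fail(rows[which(diff(tt) < 0)[1] + 1], "times not sorted within subject")
    }
    if (!any(data$EVID[rows] == 1) && any(data$EVID[rows] == 0)) {
      fail(rows[1], sprintf("subject %s has observations but no dose", id))
    }
    for (col in c("WT", "AGE", "SEX", names(SNP_LEVELS))) {
      if (length(unique(data[[col]][rows])) > 1) {
        fail(rows[1], sprintf("covariate %s varies within subject %s", col, id))
      }
    }
  }
  data
}

#' Read a study dataset from CSV
#'
#' Expects the comma-separated, header-first layout written by
#' [write_study_csv()]: one row per event, blank `AMT`/`RATE`/`DV` cells on
#' rows where they do not apply.
#'
#' @param path Path to a CSV file.
#' @return A validated `study_dataset` tibble.
#' @export
read_study_csv <- function(path) {
  data <- readr::read_csv(
    path,
    col_types = readr::cols(
      ID = readr::col_character(), TIME = readr::col_double(),
      AMT = readr::col_double(), RATE = readr::col_double(),
      EVID = readr::col_integer(), DVID = readr::col_integer(),
      DV = readr::col_double(), MDV = readr::col_integer(),
      WT = readr::col_double(), AGE = readr::col_double(),
      SEX = readr::col_integer(), SNP2578 = readr::col_character(),
      SNP1154 = readr::col_character(), SNP634 = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  study_dataset(data)
}

#' Write a study dataset to CSV
#'
#' Deterministic column order; round-trips losslessly through
#' [read_study_csv()].
#'
#' @param data A `study_dataset` (or compatible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(data, path) {
  data <- tibble::as_tibble(data)[STUDY_COLUMNS]
  readr::write_csv(data, path, na = "", progress = FALSE)
  invisible(path)
}

# Internal: split a study dataset into per-subject structures used by the
# structural and estimation layers. Converts to internal units once:
# dose amounts to nmol, observations to nM, infusion duration to days.
prep_subjects <- function(data, constants = molar_constants()) {
  data <- tibble::as_tibble(data)
  ids <- unique(data$ID)
  purrr::map(ids, function(id) {
    rows <- data[data$ID == id, ]
    doses <- rows[rows$EVID == 1, ]
    obs <- rows[rows$EVID == 0 & rows$MDV == 0, ]
    dur <- doses$AMT / doses$RATE
    y_nM <- ifelse(obs$DVID == 1,
                   mass_to_molar(obs$DV, constants$mw_drug, from = "mg/L"),
                   mass_to_molar(obs$DV, constants$mw_target, from = "ng/L"))
    list(
      id = id,
      covariates = list(
        weight = rows$WT[1], age = rows$AGE[1],
        sex = ifelse(rows$SEX[1] == 1, "M", "F"),
        snp_2578 = rows$SNP2578[1], snp_1154 = rows$SNP1154[1],
        snp_634 = rows$SNP634[1]
      ),
      dose_times = doses$TIME,
      dose_nmol = dose_mg_to_nmol(doses$AMT, constants$mw_drug),
      dose_durations = dur,
      obs_times = obs$TIME,
      obs_dvid = obs$DVID,
      obs_nM = y_nM
    )
  }) |>
    setNames(ids)
}
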