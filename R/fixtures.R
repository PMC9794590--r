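fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "schaftosim")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)
  assert_that(file.exists(p), paste("fixture not found:", file))
  p
}

.fixture_files <- c(
  table1 = "table1_model_parameters.csv",
  table2 = "table2_ckd_scaling.csv",
  table3 = "table3_rat_pk.csv",
  table4 = "table4_human_pk.csv",
  table5 = "table5_fold_errors.csv",
  table6 = "table6_population_pk.csv"
)

#' Packaged study tables
#'
#' Loads the six packaged study tables as typed tibbles:
#' * `table1` — drug and formulation parameters of the PBPK model,
#' * `table2` — CKD stage scaling fractions,
#' * `table3` — observed rat PK parameters (iv and oral TFDS),
#' * `table4` — observed human PK parameters (day 1 and day 6),
#' * `table5` — predicted/observed PK parameters with fold errors, AFE and
#'   AAFE per dose group,
#' * `table6` — predicted population PK summaries (healthy, CKD3-5,
#'   elderly; mean and 2.5/97.5 percentiles).
#'
#' @param which Optional table name (e.g. `"table5"`).
#' @return A named list of tibbles (or a single tibble when `which` is
#'   given).
#' @examples
#' load_study_tables("table5") |> head(2)
#' @export
load_study_tables <- function(which = NULL) {
  read_one <- function(file) {
    readr::read_csv(fixture_path(file), show_col_types = FALSE,
                    progress = FALSE)
  }
  if (!is.null(which)) {
    which <- match.arg(which, names(.fixture_files))
    return(read_one(.fixture_files[[which]]))
  }
  map(.fixture_files, read_one)
}

#' Schaftoside model inputs from the packaged parameter table
#'
#' Reconstructs the `pbpk_compound` and per-species formulations from the
#' packaged parameter fixture; equal to [schaftoside_defaults()] by
#' construction (asserted in the test suite).
#'
#' @return A list with `compound`, `formulation_rat`, `formulation_human`.
#' @export
schaftoside_from_fixture <- function() {
  t1 <- load_study_tables("table1")
  val <- function(p, species = "both") {
    t1$value[t1$parameter == p & t1$species == species]
  }
  list(
    compound = compound(
      name = "schaftoside", mwt = val("mwt"), logp = val("logp"),
      acidic_pka = val("acidic_pka"),
      solubility_ph7 = val("solubility_ph7"), fu = val("fu"),
      intestinal_permeability = val("intestinal_permeability"),
      organ_permeability = val("organ_permeability"),
      kidney_plasma_clearance = c(
        rat = val("kidney_plasma_clearance", "rat"),
        human = val("kidney_plasma_clearance", "human"))
    ),
    formulation_rat = formulation("suspension",
                                  t50 = val("dissolution_t50", "rat"),
                                  shape = val("dissolution_shape", "rat")),
    formulation_human = formulation("capsule",
                                    t50 = val("dissolution_t50", "human"),
                                    shape = val("dissolution_shape", "human"))
  )
}
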