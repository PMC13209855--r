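#' Packaged study tables
#'
#' The published per-formulation characterization tables of the lutein
#' microencapsulation study (mean +/- SD summaries, n = 3 analytical
#' replicates), shipped as plain-text CSVs so the reporting and
#' statistics paths can be exercised against the printed values.
#'
#' Available tables:
#' \describe{
#'   \item{moisture_solubility}{moisture content and solubility, percent}
#'   \item{oil_ee}{surface oil, total oil (g/100 g) and encapsulation
#'     efficiency (percent)}
#'   \item{density_flow}{bulk/tapped density (kg/m^3), Carr's Index
#'     (percent), Hausner Ratio}
#'   \item{diameters}{valid particle counts and size descriptors (um)}
#'   \item{lutein}{analyte concentration in powder and lipid core (ug/g)}
#'   \item{recipes}{formulation recipes: oil, emulsifier and wall-material
#'     solution masses (g) with the solution solid fraction}
#' }
#'
#' @param name one of the table names above
#' @return a data frame
#' @export
study_table <- function(name = c("moisture_solubility", "oil_ee",
                                 "density_flow", "diameters", "lutein",
                                 "recipes")) {
  name <- match.arg(name)
  file <- switch(name,
                 moisture_solubility = "table1_moisture_solubility.csv",
                 oil_ee = "table2_oil_ee.csv",
                 density_flow = "table3_density_flow.csv",
                 diameters = "table4_diameters.csv",
                 lutein = "table6_lutein.csv",
                 recipes = "table7_recipes.csv")
  path <- system.file("extdata", file, package = "capmetrics")
  if (path == "") stop_cap("packaged table not found: ", file)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recipe of one study formulation
#'
#' Builds a [formulation_recipe] from the packaged recipe table: carrier
#' oil + emulsifier + two 15% wall-material solutions (maltodextrin plus
#' gum arabic or a modified starch).
#'
#' @param formulation formulation code (e.g. `"CON"`)
#' @return a [formulation_recipe]
#' @export
study_recipe <- function(formulation) {
  tb <- study_table("recipes")
  row <- tb[tb$formulation == formulation, ]
  if (nrow(row) != 1) stop_cap("unknown formulation: ", formulation)
  formulation_recipe(
    oil_mass = row$oil_mass,
    emulsifier_mass = row$emulsifier_mass,
    solutions = data.frame(
      mass = c(row$maltodextrin_solution, row$second_solution),
      solid_fraction = rep(row$solid_fraction, 2)
    )
  )
}
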