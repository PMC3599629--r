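#' Packaged reference tables from the published instrument evaluation
#'
#' The raw 61-patient responses behind the published evaluation were never
#' deposited, so the printed summary tables ship with the package exactly as
#' printed: observed category frequencies (table 1), Mokken scalabilities
#' with bootstrap intervals, alpha and case counts (table 2), graded-response
#' item locations with standard errors (table 3), and relative item
#' information with discriminations (table 4). They serve as arithmetic
#' fixtures and as qualitative targets for the synthetic generators — not as
#' recomputation targets.
#'
#' @return A list with data frames `table1`, `table2`, `table2_summary`,
#'   `table3`, `table4`.
#' @examples
#' fx <- load_paper_fixtures()
#' subset(fx$table2, item == "MADRS4")$H  # 0.103
#' @export
load_paper_fixtures <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "scalestep", mustWork = TRUE),
    stringsAsFactors = FALSE, check.names = FALSE)
  list(table1 = rd("table1.csv"),
       table2 = rd("table2.csv"),
       table2_summary = rd("table2_summary.csv"),
       table3 = rd("table3.csv"),
       table4 = rd("table4.csv"))
}
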