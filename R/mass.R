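## Protein mass arithmetic and 1:1-complex stoichiometry bookkeeping:
## sequence masses, additive complex masses, and the "% of expected"
## statistic comparing measured (MS / SEC-MALS) against theoretical masses.

## average residue masses, Da (Expasy; residue = amino acid minus water)
.AA_AVG <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

## monoisotopic residue masses, Da
.AA_MONO <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
              C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
              H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
              M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
              T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

.H2O_AVG <- 18.01528
.H2O_MONO <- 18.010565

#' Protein mass from a one-letter sequence
#'
#' Sum of residue masses plus one water. Average masses (matching ESI-TOF
#' deconvolved masses) by default; monoisotopic behind a flag.
#'
#' @param seq one-letter amino-acid string (20 canonical letters).
#' @param monoisotopic use monoisotopic masses instead of average.
#' @return Mass in Da.
#' @examples
#' average_mass("G")    # 75.07
#' average_mass("GG")   # 132.12
#' @export
average_mass <- function(seq, monoisotopic = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop_invalid("seq must be a non-empty one-letter amino-acid string")
  aa <- strsplit(toupper(seq), "")[[1L]]
  tab <- if (monoisotopic) .AA_MONO else .AA_AVG
  bad <- setdiff(unique(aa), names(tab))
  if (length(bad))
    stop_invalid("non-canonical letters in sequence: ",
                 paste(bad, collapse = ", "))
  sum(tab[aa]) + if (monoisotopic) .H2O_MONO else .H2O_AVG
}

#' Read protein sequences from a FASTA file
#'
#' @param file FASTA path.
#' @return Named character vector of one-letter sequences.
#' @export
read_fasta_sequences <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop_invalid("no FASTA headers in ", file)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  names(seqs) <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  gsub("\\s", "", seqs)
}

#' Theoretical mass of an n-component complex
#'
#' @param components component masses, kDa (>= 1 value).
#' @return Sum, rounded to 2 decimals for reporting.
#' @examples
#' complex_theoretical_mass(c(35.87, 12.76))  # 48.63
#' @export
complex_theoretical_mass <- function(components) {
  components <- as.numeric(components)
  if (length(components) < 1L || any(!is.finite(components)) ||
      any(components <= 0))
    stop_invalid("components must be >= 1 positive masses")
  round(sum(components), 2)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Measured mass as an integer percentage of the theoretical mass
#'
#' Rounds half away from zero, matching report-table conventions.
#'
#' @param measured measured mass.
#' @param theoretical theoretical mass (> 0), same units.
#' @return Integer percentage.
#' @examples
#' percent_of_expected(48.27, 48.63)  # 99
#' percent_of_expected(41.00, 35.87)  # 114
#' @export
percent_of_expected <- function(measured, theoretical) {
  check_scalar(measured, "measured")
  if (!is.numeric(theoretical) || length(theoretical) != 1L ||
      !is.finite(theoretical) || theoretical <= 0)
    stop_invalid("theoretical must be > 0")
  as.integer(round_half_away(100 * measured / theoretical))
}

#' One species row for the summary report
#'
#' @param species species name.
#' @param measured_kda,theoretical_kda masses, kDa.
#' @param rh_nm hydrodynamic radius, nm.
#' @param rg_guinier_nm,rg_debye_nm,rg_theory_nm radius-of-gyration
#'   variants, nm.
#' @param dmax_nm,dmax_theory_nm maximum-dimension variants, nm.
#' @return A one-row data frame.
#' @export
species_summary <- function(species, measured_kda = NA, theoretical_kda = NA,
                            rh_nm = NA, rg_guinier_nm = NA,
                            rg_debye_nm = NA, rg_theory_nm = NA,
                            dmax_nm = NA, dmax_theory_nm = NA) {
  data.frame(species = species, measured_kda = measured_kda,
             theoretical_kda = theoretical_kda, rh_nm = rh_nm,
             rg_guinier_nm = rg_guinier_nm, rg_debye_nm = rg_debye_nm,
             rg_theory_nm = rg_theory_nm, dmax_nm = dmax_nm,
             dmax_theory_nm = dmax_theory_nm)
}

#' Build a mass/size summary report table
#'
#' Joins measured, fitted and theoretical quantities per species and
#' derives the "% of expected" column. Values expected in nm; entries with
#' magnitude > 100 in any size column trigger a unit-mismatch warning
#' (Å supplied where nm expected).
#'
#' @param entries list of [species_summary()] rows (or a data frame of
#'   them); may be empty.
#' @return Data frame of class `report_table` with a `percent_of_expected`
#'   column, sizes formatted at 2 decimals.
#' @export
build_report <- function(entries) {
  if (is.data.frame(entries)) entries <- list(entries)
  if (!length(entries)) {
    out <- species_summary("")[0, ]
    out$percent_of_expected <- integer(0)
    class(out) <- c("report_table", "data.frame")
    return(out)
  }
  tab <- do.call(rbind, entries)
  size_cols <- grep("_nm$", names(tab), value = TRUE)
  sizes <- unlist(tab[size_cols])
  if (any(is.finite(sizes) & abs(sizes) > 100))
    warning("size entries with magnitude > 100 look like Å, not nm")
  tab$percent_of_expected <- ifelse(
    is.finite(tab$measured_kda) & is.finite(tab$theoretical_kda),
    mapply(percent_of_expected, tab$measured_kda, tab$theoretical_kda),
    NA_integer_)
  tab[size_cols] <- lapply(tab[size_cols], function(x) round(x, 2))
  class(tab) <- c("report_table", "data.frame")
  tab
}

#' Write a report table as CSV
#' @param report a `report_table`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_report_csv <- function(report, file) {
  write.csv(as.data.frame(report), file, row.names = FALSE)
  invisible(file)
}
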