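#' Unit-conversion context
#'
#' Constants for converting heparin activity units to molarity and
#' absorbance to peptide concentration. The specific activity of the UFH
#' lot (183.5 U/mg) and the average UFH molecular weight (10900 g/mol) are
#' shipped as defaults; the cuvette path length defaults to 1 cm.
#'
#' @param ufh_specific_activity U/mg
#' @param ufh_mw g/mol
#' @param path_length cm
#' @return list of class `unit_context`
#' @export
unit_context <- function(ufh_specific_activity = 183.5, ufh_mw = 10900,
                         path_length = 1) {
  if (ufh_specific_activity <= 0 || ufh_mw <= 0 || path_length <= 0)
    stop("unit-context constants must be positive")
  structure(list(ufh_specific_activity = ufh_specific_activity,
                 ufh_mw = ufh_mw, path_length = path_length),
            class = "unit_context")
}

#' Convert UFH activity concentration to molarity
#'
#' U/ml -> mg/ml via the specific activity, then -> mol/L via the average
#' molecular weight, reported in uM. Lets heparin doses share a molar axis
#' with the peptide DTIs.
#'
#' @param u_per_ml activity concentration, U/ml (>= 0)
#' @param ctx a [unit_context()]
#' @return concentration in uM
#' @export
ufh_units_to_molar <- function(u_per_ml, ctx = unit_context()) {
  if (any(u_per_ml < 0)) stop("activity concentration must be >= 0")
  mg_per_ml <- u_per_ml / ctx$ufh_specific_activity
  (mg_per_ml / ctx$ufh_mw) * 1e6        # g/L / (g/mol) = mol/L -> uM
}

#' Molar extinction coefficient at 280 nm from a peptide sequence
#'
#' Gill-von Hippel composition rule: 1490/M/cm per tyrosine, 5500 per
#' tryptophan, 125 per cystine (disulfide-bonded cysteine pair; free
#' cysteines are assumed paired in twos). A Tyr/Trp-free peptide returns 0,
#' signalling that 280 nm quantification is impossible and a 205 nm
#' standard-curve must be used instead.
#'
#' @param sequence one-letter amino-acid string (standard 20 residues)
#' @return extinction coefficient, 1/(M cm)
#' @export
extinction_coefficient_280 <- function(sequence) {
  aa <- strsplit(toupper(gsub("[^A-Za-z]", "", sequence)), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(aa %in% valid))
    stop("unknown residue codes: ",
         paste(unique(aa[!aa %in% valid]), collapse = ", "))
  n_tyr <- sum(aa == "Y")
  n_trp <- sum(aa == "W")
  n_cystine <- sum(aa == "C") %/% 2
  1490 * n_tyr + 5500 * n_trp + 125 * n_cystine
}

#' Peptide concentration from UV absorbance (Beer-Lambert)
#'
#' @param A absorbance, AU
#' @param epsilon molar extinction coefficient, 1/(M cm) (> 0; a zero
#'   coefficient means the peptide has no aromatic chromophore and a
#'   205 nm standard curve is required, see [fit_standard_curve()])
#' @param ctx a [unit_context()] (supplies the path length)
#' @return concentration, mol/L
#' @export
conc_from_absorbance <- function(A, epsilon, ctx = unit_context()) {
  if (epsilon == 0)
    stop("zero extinction coefficient: use a standard curve (A205) instead")
  if (epsilon < 0) stop("extinction coefficient must be positive")
  A / (epsilon * ctx$path_length)
}

#' Linear standard curve for absorbance-based quantification
#'
#' OLS fit of absorbance on known concentrations for peptides lacking
#' aromatic residues (quantified at 205 nm against reference peptides of
#' similar length and composition).
#'
#' @param known_conc reference concentrations
#' @param absorbance measured absorbances of the references
#' @return list of class `standard_curve`: `intercept`, `slope`, and
#'   `predict(A)` returning concentrations in the reference unit
#' @export
fit_standard_curve <- function(known_conc, absorbance) {
  stopifnot(length(known_conc) == length(absorbance), length(known_conc) >= 2)
  fit <- stats::lm(absorbance ~ known_conc)
  b0 <- unname(stats::coef(fit)[1]); b1 <- unname(stats::coef(fit)[2])
  if (b1 <= 0) stop("standard curve slope must be positive")
  structure(list(intercept = b0, slope = b1,
                 predict = function(A) (A - b0) / b1),
            class = "standard_curve")
}

# --- CSV schemas -----------------------------------------------------------

assay_schemas <- list(
  progress_curve = c("curve_id", "time_s", "absorbance_au", "Et_nM",
                     "It_nM", "S_uM"),
  cwa_trace = c("time_s", "transmittance_pct"),
  thrombogram = c("time_min", "thrombin_nM"),
  invivo_records = c("subject_id", "dose", "response_time_min", "censored",
                     "cap_min"),
  sensorgram = c("time_s", "response_nm", "phase", "conc_nM")
)

#' Read an assay CSV with schema validation
#'
#' Comma-separated, UTF-8, mandatory header, '.' decimal; long format for
#' time series. Missing required columns are reported by name.
#'
#' @param path file path
#' @param schema one of "progress_curve", "cwa_trace", "thrombogram",
#'   "invivo_records", "sensorgram"
#' @return data frame carrying the schema's class
#' @export
read_assay_csv <- function(path, schema) {
  schema <- match.arg(schema, names(assay_schemas))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- assay_schemas[[schema]]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")))
  if ("censored" %in% names(df)) df$censored <- as.logical(df$censored)
  cls <- switch(schema,
                progress_curve = "progress_curves",
                cwa_trace = "cwa_trace",
                thrombogram = "thrombogram",
                invivo_records = "invivo_records",
                sensorgram = "sensorgram")
  structure(df, class = c(cls, "data.frame"))
}

#' Write an assay table as CSV
#'
#' The writer and [read_assay_csv()] round-trip losslessly (schema and
#' values).
#'
#' @param df data frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_assay_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
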