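#' Homeostasis Model Assessment of insulin resistance (HOMA-IR)
#'
#' `insulin * glucose / 22.5`, with insulin in uUI/mL and fasting glucose in
#' mmol/L.  Vectorized; `NA` propagates.
#'
#' @param insulin fasting insulinemia (uUI/mL), >= 0.
#' @param glucose fasting blood glucose (mmol/L), >= 0.
#' @return numeric HOMA-IR index (unitless).
#' @examples
#' homa_ir(22.5, 1.0)   # 1
#' homa_ir(21.6, 5.12)  # typical severely obese baseline
#' @export
homa_ir <- function(insulin, glucose) {
  .stop_if(any(insulin < 0, na.rm = TRUE) || any(glucose < 0, na.rm = TRUE),
           "insulin and glucose must be non-negative")
  insulin * glucose / 22.5
}

#' Metabolic-syndrome classification (IDF-style factor count)
#'
#' Counts four risk factors and classifies metabolic syndrome as at least
#' two of them: raised triglycerides (>= 1.7 mmol/L) or lipid treatment;
#' reduced HDL-cholesterol (< 1.29 mmol/L) or lipid treatment; raised blood
#' pressure (systolic >= 130 or diastolic >= 85 mmHg) or antihypertensive
#' treatment; raised fasting glucose (>= 5.6 mmol/L) or previously diagnosed
#' type-2 diabetes.  The HDL boundary is strict (`<`), the others are
#' non-strict (`>=`), as conventionally printed.
#'
#' A missing measurement with no corresponding treatment/diagnosis flag
#' leaves that factor `FALSE` and marks the row as `incomplete`.
#'
#' @param tg triglycerides, mmol/L.
#' @param hdl HDL-cholesterol, mmol/L.
#' @param sbp,dbp systolic/diastolic blood pressure, mmHg.
#' @param glucose fasting plasma glucose, mmol/L.
#' @param lipid_tx,htn_tx,t2d_dx logical flags: lipid-lowering treatment,
#'   antihypertensive treatment, prior type-2 diabetes diagnosis.
#' @return data frame with columns `factor_count` (0-4), `mets` (logical)
#'   and `incomplete` (logical).
#' @examples
#' mets_classify(tg = 1.8, hdl = 1.5, sbp = 120, dbp = 70, glucose = 5.6)
#' @export
mets_classify <- function(tg = NA, hdl = NA, sbp = NA, dbp = NA, glucose = NA,
                          lipid_tx = FALSE, htn_tx = FALSE, t2d_dx = FALSE) {
  n <- max(lengths(list(tg, hdl, sbp, dbp, glucose, lipid_tx, htn_tx, t2d_dx)))
  rep_n <- function(x) rep_len(x, n)
  tg <- rep_n(tg); hdl <- rep_n(hdl); sbp <- rep_n(sbp); dbp <- rep_n(dbp)
  glucose <- rep_n(glucose)
  lipid_tx <- rep_n(as.logical(lipid_tx)); htn_tx <- rep_n(as.logical(htn_tx))
  t2d_dx <- rep_n(as.logical(t2d_dx))
  for (v in list(tg, hdl, sbp, dbp, glucose))
    .stop_if(any(v < 0, na.rm = TRUE), "measurements must be non-negative")

  measured_or <- function(meas, flag) {
    out <- ifelse(is.na(meas), FALSE, meas)
    miss <- is.na(meas) & !flag
    list(val = out | flag, miss = miss)
  }
  f_tg <- measured_or(tg >= 1.7, lipid_tx)
  f_hdl <- measured_or(hdl < 1.29, lipid_tx)
  bp_raw <- ifelse(is.na(sbp) & is.na(dbp), NA,
                   (!is.na(sbp) & sbp >= 130) | (!is.na(dbp) & dbp >= 85))
  f_bp <- measured_or(bp_raw, htn_tx)
  f_glu <- measured_or(glucose >= 5.6, t2d_dx)

  factor_count <- f_tg$val + f_hdl$val + f_bp$val + f_glu$val
  data.frame(factor_count = as.integer(factor_count),
             mets = factor_count >= 2,
             incomplete = f_tg$miss | f_hdl$miss | f_bp$miss | f_glu$miss)
}

#' Diabetes classification
#'
#' A subject is classified diabetic if on antidiabetic treatment or if
#' fasting glycemia was at least 7 mmol/L on at least two different
#' occasions.
#'
#' @param antidiabetic_tx logical treatment flag.
#' @param fasting_glycemia numeric vector of fasting glycemia measurements
#'   (mmol/L); may be empty.
#' @return logical.
#' @examples
#' diabetes_classify(FALSE, c(7.1, 7.3))  # TRUE
#' diabetes_classify(FALSE, 7.5)          # FALSE: single occasion
#' @export
diabetes_classify <- function(antidiabetic_tx = FALSE,
                              fasting_glycemia = numeric()) {
  .stop_if(any(fasting_glycemia < 0, na.rm = TRUE),
           "glycemia values must be non-negative")
  isTRUE(as.logical(antidiabetic_tx)) ||
    sum(fasting_glycemia >= 7, na.rm = TRUE) >= 2
}

#' Add derived clinical phenotypes to a trait table
#'
#' Appends `homa_ir`, `mets` (with `mets_factors`) and, when treatment flags
#' are available, `diabetes` columns to a trait data frame.  Missing inputs
#' propagate as `NA`/`FALSE` per the component rules.
#'
#' @param traits data frame with (subsets of) columns `insulin`, `glucose`,
#'   `triglycerides`, `hdl`, `sbp`, `dbp`, and optional logical flags
#'   `lipid_tx`, `htn_tx`, `t2d_dx`, `antidiabetic_tx`.
#' @return the trait table with derived columns appended.
#' @export
add_phenotypes <- function(traits) {
  stopifnot(is.data.frame(traits))
  getcol <- function(nm, default = NA) {
    if (nm %in% names(traits)) traits[[nm]] else rep(default, nrow(traits))
  }
  if (all(c("insulin", "glucose") %in% names(traits)))
    traits$homa_ir <- homa_ir(traits$insulin, traits$glucose)
  ms <- mets_classify(tg = getcol("triglycerides"), hdl = getcol("hdl"),
                      sbp = getcol("sbp"), dbp = getcol("dbp"),
                      glucose = getcol("glucose"),
                      lipid_tx = getcol("lipid_tx", FALSE),
                      htn_tx = getcol("htn_tx", FALSE),
                      t2d_dx = getcol("t2d_dx", FALSE))
  traits$mets_factors <- ms$factor_count
  traits$mets <- ms$mets
  if ("antidiabetic_tx" %in% names(traits)) {
    traits$diabetes <- vapply(seq_len(nrow(traits)), function(i) {
      diabetes_classify(traits$antidiabetic_tx[i], getcol("glucose")[i])
    }, logical(1))
  }
  traits
}
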