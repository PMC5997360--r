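# Core-clock and CCG parameter containers.
#
# The network couples five genes; each gene's transcription is a product of
# statistical-mechanics occupancy terms: activation (1 + b x/K)/(1 + x/K),
# inhibition 1/(1 + x/K), each raised to the (fixed, integer) number of
# functional promoter elements, minus first-order degradation.  Delays are
# transcriptional delays: the lag between a gene's mRNA peak and its
# protein's regulatory action.

#' Gene names of the core-clock network, in state order
#' @export
CLOCK_GENES <- c("Bmal1", "RevErba", "Per2", "Cry1", "Dbp")

# fixed order in which parameters are passed to the compiled rhs
PARAM_ORDER <- c(
  "tau_Bmal1", "tau_RevErba", "tau_Per2", "tau_Cry1", "tau_Dbp",
  "d_Bmal1", "d_RevErba", "d_Per2", "d_Cry1", "d_Dbp",
  "ar1", "ar4",
  "cr2", "cr3", "cr4", "cr5",
  "gr2", "gr3", "gr4", "gr5",
  "b2", "b3", "b4", "b5",
  "ba2", "ba3", "ba4", "ba5",
  "f2", "f3", "f4",
  "fa2", "fa3", "fa4")

# dissociation constants, fold changes: shared by all tissues (fixed to
# previously published values, never fitted here)
.FIXED_CORE <- c(
  ar1 = 4.05, ar4 = 1.1,
  cr2 = 1.83, cr3 = 33.5, cr4 = 6.63, cr5 = 0.99,
  gr2 = 80.2, gr3 = 0.37, gr4 = 0.51, gr5 = 1.02,
  b2 = 3.26, b3 = 3.69, b4 = 1.35, b5 = 12.87,
  ba2 = 0.51, ba3 = 14.78, ba4 = 1.06, ba5 = 0.01,
  f2 = 1.23, f3 = 11.69, f4 = 32.2,
  fa2 = 0.19, fa3 = 0.58, fa4 = 1.61)

# per-tissue transcriptional delays (h) and degradation rates (1/h)
.TISSUE_RATES <- list(
  Liver = c(tau_Bmal1 = 4.89, tau_RevErba = 0.66, tau_Per2 = 4.00,
            tau_Cry1 = 4.00, tau_Dbp = 3.00,
            d_Bmal1 = 0.58, d_RevErba = 0.61, d_Per2 = 0.24,
            d_Cry1 = 0.18, d_Dbp = 0.63),
  Muscle = c(tau_Bmal1 = 4.03, tau_RevErba = 1.79, tau_Per2 = 3.89,
             tau_Cry1 = 3.08, tau_Dbp = 2.35,
             d_Bmal1 = 0.37, d_RevErba = 0.69, d_Per2 = 0.35,
             d_Cry1 = 0.21, d_Dbp = 0.49),
  Adipose = c(tau_Bmal1 = 7.41, tau_RevErba = 0.55, tau_Per2 = 3.83,
              tau_Cry1 = 3.48, tau_Dbp = 2.20,
              d_Bmal1 = 0.35, d_RevErba = 0.62, d_Per2 = 0.32,
              d_Cry1 = 0.19, d_Dbp = 0.38),
  Lung = c(tau_Bmal1 = 7.63, tau_RevErba = 0.51, tau_Per2 = 3.98,
           tau_Cry1 = 3.16, tau_Dbp = 2.46,
           d_Bmal1 = 0.37, d_RevErba = 0.55, d_Per2 = 0.29,
           d_Cry1 = 0.20, d_Dbp = 0.48),
  `All-tissues` = c(tau_Bmal1 = 6.28, tau_RevErba = 0.56, tau_Per2 = 3.95,
                    tau_Cry1 = 3.84, tau_Dbp = 3.00,
                    d_Bmal1 = 0.39, d_RevErba = 0.58, d_Per2 = 0.27,
                    d_Cry1 = 0.22, d_Dbp = 0.42))

#' Construct a core-clock parameter set
#'
#' All 34 parameters of the five-gene network: five transcriptional delays
#' (hours), five degradation rates (1/hour), and the fixed dissociation
#' constants and fold changes.  Values omitted from `...` default to the
#' published shared constants, so typically only delays and degradation
#' rates are supplied.  Extra named entries not used by the network are
#' retained (useful for dummy-parameter sensitivity checks) but ignored by
#' the dynamics.
#'
#' @param ... named numeric parameter values overriding defaults.
#' @param base optional named numeric vector/list used as the starting set.
#' @return named list of class `core_clock_params`.
#' @export
core_clock_parameters <- function(..., base = NULL) {
  p <- as.list(.FIXED_CORE)
  if (!is.null(base)) p[names(base)] <- as.list(base)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameters must be named")
    p[names(dots)] <- dots
  }
  missing <- setdiff(PARAM_ORDER, names(p))
  if (length(missing))
    stop("missing core-clock parameters: ", paste(missing, collapse = ", "))
  core <- unlist(p[PARAM_ORDER])
  if (any(!is.finite(core))) stop("non-finite core-clock parameter")
  if (any(core <= 0))
    stop("core-clock parameters must be strictly positive: ",
         paste(PARAM_ORDER[core <= 0], collapse = ", "))
  structure(p, class = "core_clock_params")
}

#' Published per-tissue core-clock parameter sets
#'
#' Delays and degradation rates estimated per tissue (Liver, Muscle,
#' Adipose, Lung) or jointly ("All-tissues" consensus), combined with the
#' shared fixed constants.
#'
#' @param tissue one of `"Liver"`, `"Muscle"`, `"Adipose"`, `"Lung"`,
#'   `"All-tissues"`.
#' @return `core_clock_params` list.
#' @export
clock_params <- function(tissue = "All-tissues") {
  tissue <- match.arg(tissue, names(.TISSUE_RATES))
  core_clock_parameters(base = .TISSUE_RATES[[tissue]])
}

#' Names of tissues with published parameter columns
#' @export
clock_tissues <- function() names(.TISSUE_RATES)

# flatten to the fixed-order numeric vector consumed by the compiled rhs
param_vector <- function(params) {
  stopifnot(inherits(params, "core_clock_params") || is.list(params))
  v <- unlist(params[PARAM_ORDER])
  if (length(v) != length(PARAM_ORDER) || any(!is.finite(v)))
    stop("invalid core-clock parameter set")
  v
}

#' Construct a clock-controlled gene (CCG) parameter set
#'
#' A CCG is a single equation forced by the delayed core-clock trajectory:
#' Ebox terms (BMAL1 activation, PER2 and CRY1 inhibition, all with exponent
#' `n1`), an RRE term (REV-ERBa inhibition, exponent `n2`) and a Dbox term
#' (DBP activation, exponent `n3`), minus first-order degradation.  A zero
#' element count makes the corresponding term identically 1.
#'
#' @param b,f fold changes (dimensionless, > 0).
#' @param ba,cr,gr,ar,fa dissociation constants (concentration, > 0).
#' @param d degradation rate (1/hour, > 0).
#' @param n1,n2,n3 non-negative integer Ebox / RRE / Dbox element counts.
#' @param gene optional gene label.
#' @return list of class `ccg_params`.
#' @export
ccg_parameters <- function(b = 2, ba = 1, cr = 1, gr = 1, ar = 1,
                           f = 2, fa = 1, d = 0.3,
                           n1 = 0L, n2 = 0L, n3 = 0L, gene = "CCG") {
  cont <- c(b = b, ba = ba, cr = cr, gr = gr, ar = ar, f = f, fa = fa, d = d)
  if (any(!is.finite(cont)) || any(cont <= 0))
    stop("continuous CCG parameters must be finite and > 0")
  n <- c(n1, n2, n3)
  if (any(!is.finite(n)) || any(n < 0) || any(n != round(n)))
    stop("element counts n1, n2, n3 must be non-negative integers")
  structure(list(b = b, ba = ba, cr = cr, gr = gr, ar = ar, f = f, fa = fa,
                 d = d, n1 = as.integer(n1), n2 = as.integer(n2),
                 n3 = as.integer(n3), gene = gene),
            class = "ccg_params")
}

#' Bundle a tissue label with core-clock parameters
#'
#' @param tissue tissue label.
#' @param params `core_clock_params`.
#' @return list of class `tissue_model` with a fixed gene -> state mapping.
#' @export
tissue_model <- function(tissue, params = clock_params(tissue)) {
  stopifnot(is.character(tissue), length(tissue) == 1)
  structure(list(tissue = tissue, params = params,
                 genes = setNames(seq_along(CLOCK_GENES), CLOCK_GENES)),
            class = "tissue_model")
}

#' @export
print.core_clock_params <- function(x, ...) {
  cat("Core-clock parameters\n")
  v <- unlist(x[PARAM_ORDER])
  cat("  delays (h):      ",
      paste(sprintf("%s=%.3g", CLOCK_GENES, v[1:5]), collapse = " "), "\n")
  cat("  degradation (1/h):",
      paste(sprintf("%s=%.3g", CLOCK_GENES, v[6:10]), collapse = " "), "\n")
  cat("  plus", length(PARAM_ORDER) - 10L, "fixed constants\n")
  invisible(x)
}
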