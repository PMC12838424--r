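#' Elemental formulas over C, H, N, O, P
#'
#' Formulas are named integer vectors over the five elements that occur in
#' (modified) nucleosides and nucleotides. Arithmetic is elementwise;
#' subtraction below zero is an error.
#'
#' @param x Formula string like `"C5H8O4"` (element symbols followed by
#'   optional counts), or a named numeric vector.
#' @return Named integer vector with elements C, H, N, O, P.
#' @export
parse_formula <- function(x) {
  out <- stats::setNames(integer(5L), c("C", "H", "N", "O", "P"))
  if (is.numeric(x)) {
    bad <- setdiff(names(x), names(out))
    if (length(bad)) stop(sprintf("unsupported element(s): %s", paste(bad, collapse = ", ")))
    out[names(x)] <- as.integer(x)
    return(out)
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(out)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1L]]
  toks <- regmatches(x, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop(sprintf("cannot parse formula '%s'", x))
  }
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(out)) stop(sprintf("unsupported element '%s' in '%s'", el, x))
    out[el] <- out[el] + n
  }
  out
}

#' @rdname parse_formula
#' @param a,b Formulas (strings or parsed vectors).
#' @export
formula_add <- function(a, b) parse_formula(a) + parse_formula(b)

#' @rdname parse_formula
#' @export
formula_subtract <- function(a, b) {
  r <- parse_formula(a) - parse_formula(b)
  if (any(r < 0L)) {
    stop(sprintf("subtraction yields negative count for %s",
                 paste(names(r)[r < 0L], collapse = ", ")))
  }
  r
}

#' @rdname parse_formula
#' @param f A parsed formula.
#' @export
formula_string <- function(f) {
  f <- parse_formula(f)
  paste0(vapply(names(f)[f > 0L], function(el)
    if (f[el] == 1L) el else sprintf("%s%d", el, f[el]), ""), collapse = "")
}

# IUPAC monoisotopic element masses (Da)
.ELEMENT_MASS <- c(C = 12.000000, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151)
.PROTON_MASS <- 1.00728

#' Monoisotopic mass of a formula
#' @param formula Formula string or parsed vector.
#' @return Mass in Da (0 for the empty formula).
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  sum(f * .ELEMENT_MASS[names(f)])
}

#' m/z of a singly charged adduct
#'
#' `[M+H]+` adds, `[M-H]-` removes, one proton (1.00728 Da). All species in
#' this package are singly charged.
#'
#' @param formula Formula string or parsed vector.
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @return m/z value.
#' @export
adduct_mz <- function(formula, adduct = c("[M+H]+", "[M-H]-")) {
  adduct <- match.arg(adduct)
  m <- monoisotopic_mass(formula)
  if (adduct == "[M+H]+") m + .PROTON_MASS else m - .PROTON_MASS
}

#' Shipped species, modification-delta and neutral-loss libraries
#'
#' Small extensible libraries of named formulas: free bases, deoxynucleosides
#' and deoxynucleotides plus UDP-xylose (`mod_base_library()`); net mass
#' deltas of base decorations (`mod_delta_library()`; `pentosyl` is a pentose
#' attached with loss of water plus an extra oxygen, i.e. the net composition
#' of a glycosidically bound pentose on an oxygen, with no structural claim);
#' and neutral losses seen in tandem-MS fragmentation
#' (`neutral_loss_library()`).
#'
#' @param extra Optional named character vector of additional
#'   `name = formula` entries.
#' @return Named list of parsed formulas.
#' @export
mod_base_library <- function(extra = NULL) {
  .library(c(
    cytosine = "C4H5N3O",
    "5hmC" = "C5H7N3O2",
    dC = "C9H13N3O4",
    dCMP = "C9H14N3O7P",
    dTMP = "C10H15N2O8P",
    dAMP = "C10H14N5O6P",
    dGMP = "C10H14N5O7P",
    "UDP-xylose" = "C14H22N2O16P2"
  ), extra)
}

#' @rdname mod_base_library
#' @export
mod_delta_library <- function(extra = NULL) {
  .library(c(
    pentosyl = "C5H8O4",
    deoxypentosyl = "C5H8O3",
    glucosyl = "C6H10O5",
    methyl = "CH2",
    hydroxymethyl = "CH2O"
  ), extra)
}

#' @rdname mod_base_library
#' @export
neutral_loss_library <- function(extra = NULL) {
  .library(c(
    water = "H2O",
    deoxyribose = "C5H8O3",
    pentosyl = "C5H8O3",
    phosphate = "HPO3"
  ), extra)
}

.library <- function(entries, extra) {
  if (!is.null(extra)) entries <- c(entries, extra)
  lapply(as.list(entries), parse_formula)
}

#' Explain an observed m/z by base species plus optional modification delta
#'
#' Enumerates all (base, delta) pairs — including the bare base with no
#' delta — whose theoretical adduct m/z lies within `tol_da` of the
#' observation, sorted by absolute error. The tolerance is an explicit
#' parameter because printed instrument m/z carry calibration offsets of a
#' few mDa (four-decimal peaks) up to a few tens of mDa (two-decimal peaks).
#'
#' @param observed_mz Observed m/z value.
#' @param base_library Named list of base formulas (default
#'   [mod_base_library()]).
#' @param delta_library Named list of delta formulas (default
#'   [mod_delta_library()]).
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @param tol_da Match tolerance in Da (> 0).
#' @return data.frame (possibly empty) with columns `base`, `delta`
#'   (`"(none)"` for the bare species), `formula`, `theoretical_mz`,
#'   `observed_mz`, `abs_error`, `adduct`, sorted by `abs_error`.
#' @export
explain_peak <- function(observed_mz, base_library = mod_base_library(),
                         delta_library = mod_delta_library(),
                         adduct = c("[M+H]+", "[M-H]-"), tol_da = 0.005) {
  adduct <- match.arg(adduct)
  stopifnot(tol_da >= 0)
  deltas <- c(list("(none)" = parse_formula("")), delta_library)
  rows <- list()
  for (bn in names(base_library)) {
    for (dn in names(deltas)) {
      f <- base_library[[bn]] + deltas[[dn]]
      mz <- adduct_mz(f, adduct)
      err <- abs(mz - observed_mz)
      if (err <= tol_da) {
        rows[[length(rows) + 1L]] <- data.frame(
          base = bn, delta = dn, formula = formula_string(f),
          theoretical_mz = mz, observed_mz = observed_mz,
          abs_error = err, adduct = adduct, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(base = character(0), delta = character(0),
                      formula = character(0), theoretical_mz = numeric(0),
                      observed_mz = numeric(0), abs_error = numeric(0),
                      adduct = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$abs_error), , drop = FALSE]
}

#' Assign tandem-MS fragment peaks by neutral losses from a parent
#'
#' Tries every single neutral loss and every chained pair of losses (depth
#' 2) from `loss_library` against each fragment m/z; losses exceeding the
#' parent's composition are skipped. Fragments with no assignment within
#' `tol_da` are flagged.
#'
#' @param parent Parent formula (string or parsed).
#' @param parent_adduct `"[M+H]+"` or `"[M-H]-"` (the fragment keeps the
#'   charge).
#' @param fragment_mzs Numeric vector of observed fragment m/z.
#' @param loss_library Named list of neutral-loss formulas (default
#'   [neutral_loss_library()]).
#' @param tol_da Match tolerance in Da (> 0).
#' @return List with `assignments` (data.frame: `fragment_mz`, `losses`,
#'   `formula`, `theoretical_mz`, `abs_error`, sorted by fragment then
#'   error) and `unassigned` (numeric vector of unexplained fragment m/z).
#' @export
explain_fragments <- function(parent, parent_adduct = c("[M+H]+", "[M-H]-"),
                              fragment_mzs, loss_library = neutral_loss_library(),
                              tol_da = 0.005) {
  parent_adduct <- match.arg(parent_adduct)
  stopifnot(tol_da >= 0)
  parent <- parse_formula(parent)
  # candidate products: single losses, then ordered-insensitive chains of two
  cands <- list()
  ln <- names(loss_library)
  for (i in seq_along(ln)) {
    d1 <- parent - loss_library[[ln[i]]]
    if (any(d1 < 0L)) next
    cands[[ln[i]]] <- d1
    for (j in i:length(ln)) {
      d2 <- d1 - loss_library[[ln[j]]]
      if (any(d2 < 0L)) next
      cands[[paste(ln[i], ln[j], sep = " + ")]] <- d2
    }
  }
  rows <- list()
  unassigned <- numeric(0)
  for (mz in fragment_mzs) {
    hit <- FALSE
    for (cn in names(cands)) {
      th <- adduct_mz(cands[[cn]], parent_adduct)
      err <- abs(th - mz)
      if (err <= tol_da) {
        hit <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          fragment_mz = mz, losses = cn,
          formula = formula_string(cands[[cn]]),
          theoretical_mz = th, abs_error = err, stringsAsFactors = FALSE)
      }
    }
    if (!hit) unassigned <- c(unassigned, mz)
  }
  assignments <- if (length(rows)) {
    out <- do.call(rbind, rows)
    out[order(out$fragment_mz, out$abs_error), , drop = FALSE]
  } else {
    data.frame(fragment_mz = numeric(0), losses = character(0),
               formula = character(0), theoretical_mz = numeric(0),
               abs_error = numeric(0), stringsAsFactors = FALSE)
  }
  list(assignments = assignments, unassigned = unassigned)
}
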