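# Monoisotopic masses of the lightest (principal) isotope, Da
# (CODATA/NIST atomic mass evaluation, >= 6 decimals).
.element_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100,
  F = 18.99840322,
  Na = 22.9897692809,
  K = 38.96370668,
  Cl = 34.96885268,
  Br = 78.9183371,
  I = 126.904473,
  Si = 27.9769265325,
  Se = 79.9165213
)

PROTON_MASS <- 1.00727646688
ELECTRON_MASS <- 0.00054857990

#' Parse a Hill-style molecular formula
#'
#' @param formula string such as `"C5H4N4"` or `"C18H18O6N3P3F24"`.
#' @return Named integer vector of element counts (repeated element
#'   symbols are summed).
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || !nzchar(formula)) {
    abort("formula must be a non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (covered != nchar(formula) || m[1] != 1) {
    # locate first unparsed character
    pos <- 1L
    for (i in seq_along(m)) {
      if (m[i] != pos) break
      pos <- pos + attr(m, "match.length")[i]
    }
    abort("cannot parse formula '", formula, "' at position ", pos)
  }
  els <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(els, names(.element_masses))
  if (length(unknown) > 0) {
    pos <- m[match(unknown[1], els)]
    abort("unknown element '", unknown[1], "' in formula '", formula,
          "' at position ", pos)
  }
  out <- tapply(counts, els, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Canonical Hill notation of parsed element counts
#'
#' Carbon first, hydrogen second, remaining elements alphabetically.
#'
#' @param counts named integer vector as from [parse_formula()].
#' @return Formula string.
#' @export
format_formula <- function(counts) {
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1) e else paste0(e, counts[[e]])
  }, ""), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Neutral mass is the sum of principal-isotope masses; the protonated
#' cation `[M+H]+` adds one proton mass (1.007276 Da, not the mass of a
#' hydrogen atom); an even-electron cation of the formula itself (e.g.
#' an acylium fragment) subtracts one electron mass.
#'
#' @param formula Hill-style formula string.
#' @param charge_mode `"neutral"`, `"protonated_cation"` (`[M+H]+`) or
#'   `"cation_minus_electron"` (`[M]+`).
#' @return Mass in Da (neutral) or m/z (singly charged cations).
#' @export
monoisotopic_mass <- function(formula,
                              charge_mode = c("neutral", "protonated_cation",
                                              "cation_minus_electron")) {
  charge_mode <- match.arg(charge_mode)
  counts <- parse_formula(formula)
  mass <- sum(.element_masses[names(counts)] * counts)
  switch(charge_mode,
    neutral = mass,
    protonated_cation = mass + PROTON_MASS,
    cation_minus_electron = mass - ELECTRON_MASS
  )
}

#' Relative mass error in parts per million
#'
#' `1e6 * (measured - theoretical) / theoretical`.
#'
#' @param measured,theoretical masses in Da; `theoretical` must be > 0.
#' @return ppm error (signed).
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) abort("theoretical mass must be > 0")
  1e6 * (measured - theoretical) / theoretical
}

#' Load a compound database from TSV
#'
#' Columns: `name`, `formula`, `class` and optionally `mass` (checked
#' against the formula to 1e-6 Da; computed from the formula when
#' absent). The packaged database is a small desk-scale stand-in for the
#' large public metabolite databases, covering the plasma metabolites of
#' interest (guanidinosuccinic acid, bile compounds, sphingoid-base
#' phosphates, acylcarnitines, lysophospholipids) plus decoys.
#'
#' @param path TSV path; default = the packaged database.
#' @return data.frame of class `compound_db` with columns `name`,
#'   `formula`, `class`, `mass`.
#' @export
read_compound_db <- function(path = NULL) {
  path <- path %||% system.file("extdata", "compound_db.tsv",
                                package = "plasmafp", mustWork = TRUE)
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("name", "formula", "class")
  if (!all(req %in% names(db))) {
    abort("compound db needs columns: ", paste(req, collapse = ", "))
  }
  calc <- vapply(db$formula, monoisotopic_mass, 0, USE.NAMES = FALSE)
  if ("mass" %in% names(db)) {
    off <- abs(db$mass - calc) > 1e-6
    if (any(off)) {
      abort("db mass inconsistent with formula for: ",
            paste(db$name[off], collapse = ", "))
    }
  }
  db$mass <- calc
  class(db) <- c("compound_db", "data.frame")
  db
}

#' @rdname read_compound_db
#' @export
default_compound_db <- function() read_compound_db()

#' Search a compound database by accurate neutral mass
#'
#' @param neutral_mass measured neutral mass, Da.
#' @param db a `compound_db` (default: packaged database).
#' @param tol_ppm match window in ppm (default 15).
#' @return data.frame of hits (`name`, `formula`, `class`,
#'   `theoretical_mass`, `measured_mass`, `ppm_error`) sorted by absolute
#'   ppm error, ties broken by name; empty when nothing matches.
#' @export
search_mass <- function(neutral_mass, db = default_compound_db(),
                        tol_ppm = 15) {
  if (!is_number(tol_ppm) || tol_ppm <= 0) abort("tol_ppm must be > 0")
  if (nrow(db) == 0) {
    return(data.frame(name = character(), formula = character(),
                      class = character(), theoretical_mass = numeric(),
                      measured_mass = numeric(), ppm_error = numeric()))
  }
  err <- ppm_error(neutral_mass, db$mass)
  hit <- abs(err) <= tol_ppm
  out <- data.frame(
    name = db$name[hit], formula = db$formula[hit], class = db$class[hit],
    theoretical_mass = db$mass[hit],
    measured_mass = rep(neutral_mass, sum(hit)),
    ppm_error = err[hit]
  )
  out <- out[order(abs(out$ppm_error), out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct an MS/MS class-confirmation rule
#'
#' @param class_name compound class confirmed by the rule.
#' @param peaks data.frame with columns `kind` (`"absolute"` m/z or
#'   `"neutral_loss"` from the precursor), `value` (m/z) and `tolerance`
#'   (m/z, > 0).
#' @param min_matches minimum number of required peaks that must be found.
#' @return A `fragment_rule`.
#' @export
fragment_rule <- function(class_name, peaks, min_matches = nrow(peaks)) {
  stopifnot(is.data.frame(peaks),
            all(c("kind", "value", "tolerance") %in% names(peaks)))
  if (!all(peaks$kind %in% c("absolute", "neutral_loss"))) {
    abort("peak kind must be 'absolute' or 'neutral_loss'")
  }
  if (any(peaks$tolerance <= 0)) abort("tolerances must be > 0")
  structure(list(class_name = class_name, peaks = peaks,
                 min_matches = min_matches),
            class = "fragment_rule")
}

#' Diagnostic fragment rules for the study's discriminating lipid classes
#'
#' Acylcarnitines: trimethylamine-related 60.08 (`[C3H9N+H]+`) and the
#' acylium-type 85.03 (`[C4H5O2]+`), both required.
#' Lysophosphatidylcholines: phosphocholine 184.07, choline 104.11 and
#' 86.1, at least two required. Lysophosphatidylethanolamines: neutral
#' loss of phosphoethanolamine, 141.02 Da from the precursor.
#'
#' @param tolerance m/z window per peak (default 0.02).
#' @return Named list of `fragment_rule`s.
#' @export
default_fragment_rules <- function(tolerance = 0.02) {
  list(
    acylcarnitine = fragment_rule(
      "acylcarnitine",
      data.frame(kind = "absolute",
                 value = c(60.0808, 85.0284),
                 tolerance = tolerance),
      min_matches = 2
    ),
    lysoPC = fragment_rule(
      "lysoPC",
      data.frame(kind = "absolute",
                 value = c(184.0733, 104.1070, 86.0964),
                 tolerance = tolerance),
      min_matches = 2
    ),
    lysoPE = fragment_rule(
      "lysoPE",
      data.frame(kind = "neutral_loss", value = 141.0191,
                 tolerance = tolerance),
      min_matches = 1
    )
  )
}

#' Match an MS/MS spectrum against class-confirmation rules
#'
#' A class matches when at least `min_matches` of its required peaks are
#' present: absolute peaks within tolerance of the stated m/z,
#' neutral-loss peaks within tolerance of `precursor - loss`.
#'
#' @param spectrum an `msms_spectrum` (see [read_spectrum()]).
#' @param rules list of [fragment_rule()]s; default
#'   [default_fragment_rules()].
#' @param mz_tol fallback m/z tolerance when a rule peak has none.
#' @return Character vector of matched class names (possibly empty).
#' @export
match_fragment_rules <- function(spectrum, rules = default_fragment_rules(),
                                 mz_tol = 0.02) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  if (!is_number(mz_tol) || mz_tol <= 0) abort("mz_tol must be > 0")
  mz <- spectrum$peaks$mz
  if (length(mz) == 0) return(character(0))
  matched <- vapply(rules, function(r) {
    targets <- ifelse(r$peaks$kind == "absolute", r$peaks$value,
                      spectrum$precursor_mz - r$peaks$value)
    tol <- ifelse(is.na(r$peaks$tolerance), mz_tol, r$peaks$tolerance)
    hits <- vapply(seq_along(targets), function(i) {
      any(abs(mz - targets[i]) <= tol[i])
    }, TRUE)
    sum(hits) >= r$min_matches
  }, TRUE)
  vapply(rules[matched], `[[`, "", "class_name")
}

#' Annotate significant features by accurate mass and MS/MS rules
#'
#' Joins each significant feature of a two-group comparison to its
#' accurate-mass database hits (best hit reported, `"unknown"` when there
#' is none) and, when an MS/MS spectrum is supplied for the feature, to
#' the fragment-rule classes it confirms. The emitted report mirrors the
#' identification-table layout of a fingerprinting study: compound,
#' retention time, measured mass, ppm error, percent change, p-value and
#' QC coefficient of variation.
#'
#' @param results a `comparison_result` from [compare_groups()].
#' @param table the raw-scale [feature_table()] the comparison came from
#'   (used for the QC CV column when QC samples are present).
#' @param db a `compound_db`.
#' @param spectra optional named list of `msms_spectrum` keyed by
#'   feature id.
#' @param tol_ppm accurate-mass window (default 15 ppm).
#' @param mz_tol fragment m/z window (default 0.02).
#' @param alpha significance cut for inclusion (default: the comparison's
#'   alpha).
#' @return data.frame of class `annotation_report`, one row per
#'   significant feature: `feature_id`, `compound`, `compound_class`,
#'   `class_confirmed`, `rt_min`, `measured_mass_da`, `ppm_error`,
#'   `pct_change`, `p`, `q`, `cv_qc_percent`.
#' @export
annotate_results <- function(results, table, db = default_compound_db(),
                             spectra = NULL, tol_ppm = 15, mz_tol = 0.02,
                             alpha = NULL) {
  stopifnot(inherits(results, "comparison_result"),
            inherits(table, "feature_table"))
  alpha <- alpha %||% attr(results, "alpha")
  sig <- as.data.frame(results)[results$p <= alpha, , drop = FALSE]

  qc_cols <- table$samples$label == "QC"
  cv_lookup <- if (any(qc_cols)) {
    stats::setNames(
      apply(table$intensities[, qc_cols, drop = FALSE], 1, qc_cv),
      table$features$feature_id
    )
  } else {
    NULL
  }

  rows <- lapply(seq_len(nrow(sig)), function(i) {
    hits <- search_mass(sig$neutral_mass_da[i], db, tol_ppm)
    spec <- spectra[[sig$feature_id[i]]]
    confirmed_classes <- if (!is.null(spec)) {
      match_fragment_rules(spec, mz_tol = mz_tol)
    } else {
      character(0)
    }
    known <- nrow(hits) > 0
    data.frame(
      feature_id = sig$feature_id[i],
      compound = if (known) hits$name[1] else "unknown",
      compound_class = if (known) hits$class[1] else "unknown",
      class_confirmed = known && hits$class[1] %in% confirmed_classes,
      rt_min = sig$rt_min[i],
      measured_mass_da = sig$neutral_mass_da[i],
      ppm_error = if (known) hits$ppm_error[1] else NA_real_,
      pct_change = sig$pct_change[i],
      p = sig$p[i],
      q = sig$q[i],
      cv_qc_percent = if (!is.null(cv_lookup)) {
        unname(cv_lookup[sig$feature_id[i]])
      } else {
        NA_real_
      }
    )
  })
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      feature_id = character(), compound = character(),
      compound_class = character(), class_confirmed = logical(),
      rt_min = numeric(), measured_mass_da = numeric(),
      ppm_error = numeric(), pct_change = numeric(), p = numeric(),
      q = numeric(), cv_qc_percent = numeric()
    )
  }
  rownames(out) <- NULL
  structure(out, groups = attr(results, "groups"),
            class = c("annotation_report", "data.frame"))
}
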