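#' Linguistic term scale
#'
#' An ordered set of linguistic terms with interior cut points on the min-max
#' normalized feature range. The default five-term scale follows the unusual
#' but fixed ordering Low < Lower < Medium < Higher < High with equal-width
#' bins; domain experts may supply their own terms and edges.
#'
#' @param terms Ordered character vector of term names (default 5 terms).
#' @param edges Strictly increasing interior cut points in `(0, 1)`, one fewer
#'   than `terms`.
#' @return An object of class `linguistic_scale`.
#' @export
linguistic_scale <- function(terms = c("Low", "Lower", "Medium", "Higher", "High"),
                             edges = c(0.2, 0.4, 0.6, 0.8)) {
  if (length(terms) != length(edges) + 1L) {
    stop("need exactly one more term than interior edges")
  }
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be strictly increasing")
  if (any(edges <= 0) || any(edges >= 1)) stop("edges must lie in (0, 1)")
  structure(list(terms = as.character(terms), edges = as.numeric(edges)),
            class = "linguistic_scale")
}

#' Assign linguistic terms to active antecedent clauses
#'
#' Each active (rule, feature) Gaussian center is min-max normalized by that
#' feature's training-data range and mapped through the scale's bins to a
#' term. Centers outside the training range clamp to the extreme terms; a
#' zero-range feature maps to the middle term with a warning.
#'
#' @param antecedent A fitted `antecedent_model` (activation mask applied).
#' @param data The training [feature_matrix()] providing per-feature ranges.
#' @param scale A [linguistic_scale()].
#' @return A list with one data frame per rule: columns `feature`, `term`,
#'   `center` and `normalized`.
#' @export
assign_linguistic_terms <- function(antecedent, data, scale = linguistic_scale()) {
  data <- as_feature_matrix(data)
  X <- data$values
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  mid <- ceiling(length(scale$terms) / 2)
  K <- nrow(antecedent$centers)
  lapply(seq_len(K), function(k) {
    act <- which(antecedent$active[k, ])
    term <- character(length(act))
    norm <- numeric(length(act))
    for (a in seq_along(act)) {
      j <- act[a]
      rng <- hi[j] - lo[j]
      if (rng < 1e-12) {
        warning(sprintf("feature '%s' has zero range; assigning middle term",
                        colnames(X)[j]))
        term[a] <- scale$terms[mid]
        norm[a] <- NA_real_
      } else {
        t0 <- (antecedent$centers[k, j] - lo[j]) / rng
        norm[a] <- t0
        t0 <- min(max(t0, 0), 1)
        term[a] <- scale$terms[findInterval(t0, scale$edges) + 1L]
      }
    }
    data.frame(feature = colnames(X)[act], term = term,
               center = unname(antecedent$centers[k, act]),
               normalized = norm, stringsAsFactors = FALSE)
  })
}

#' Render the linguistic rule base
#'
#' Produces one row per rule in the classical TSK form: an antecedent string
#' "If <feature> is <Term> ∧ ..." over the rule's active features,
#' followed by the consequent coefficients printed at 4 decimal places.
#' Ordering (rule index, then feature index) and formatting are deterministic,
#' so re-rendering the same model is byte-identical.
#'
#' @param classifier A fitted `tsk_classifier`.
#' @param clauses Optional precomputed clause lists from
#'   [assign_linguistic_terms()]; when omitted, `data` must be given.
#' @param data Training data used to derive clauses when `clauses` is `NULL`.
#' @param scale A [linguistic_scale()] used when deriving clauses.
#' @return An object of class `tsk_rule_base`: a list with per-rule
#'   `antecedent` strings, `consequent` coefficient vectors and `clauses`.
#'   Use [format_rule_base()] for text, markdown or JSON output.
#' @export
render_rule_base <- function(classifier, clauses = NULL, data = NULL,
                             scale = linguistic_scale()) {
  if (is.null(clauses)) {
    if (is.null(data)) stop("either clauses or data must be supplied")
    clauses <- assign_linguistic_terms(classifier$antecedent, data, scale)
  }
  K <- nrow(classifier$antecedent$centers)
  if (length(clauses) != K) stop("clause list does not match rule count")
  antecedent_strings <- vapply(clauses, function(cl) {
    paste0("If ", paste(sprintf("%s is %s", cl$feature, cl$term),
                        collapse = " \u2227 "))
  }, character(1L))
  structure(list(antecedents = antecedent_strings,
                 consequents = classifier$consequent$coefficients,
                 clauses = clauses, mode = classifier$consequent$mode),
            class = "tsk_rule_base")
}

#' Format a rule base as text, markdown or JSON
#'
#' @param rules A `tsk_rule_base` from [render_rule_base()].
#' @param format One of `"text"`, `"markdown"`, `"json"`.
#' @return A character vector of lines (`text`, `markdown`) or a JSON string.
#' @export
format_rule_base <- function(rules, format = c("text", "markdown", "json")) {
  format <- match.arg(format)
  coef_str <- vapply(rules$consequents, function(p) {
    paste0("[", paste(sprintf("%.4f", p), collapse = ", "), "]")
  }, character(1L))
  if (format == "json") {
    obj <- lapply(seq_along(rules$antecedents), function(k) {
      list(rule = k, antecedent = rules$antecedents[k],
           clauses = rules$clauses[[k]][, c("feature", "term")],
           consequent = round(unlist(rules$consequents[[k]]), 4))
    })
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 4)))
  }
  if (format == "markdown") {
    c("| Rule | Antecedent | Consequent |",
      "| --- | --- | --- |",
      sprintf("| %d | %s | %s |", seq_along(rules$antecedents),
              rules$antecedents, coef_str))
  } else {
    sprintf("Rule %d: %s  then  f(x) = %s",
            seq_along(rules$antecedents), rules$antecedents, coef_str)
  }
}

#' @export
print.tsk_rule_base <- function(x, ...) {
  cat(format_rule_base(x, "text"), sep = "\n")
  invisible(x)
}

#' Model-complexity accounting
#'
#' Counts the trainable parameters of a TSK classifier: each active feature of
#' a rule contributes 2 antecedent parameters (Gaussian center and spread),
#' and each rule's linear consequent contributes `d_k + 1` parameters in
#' reduced mode (its `d_k` active features plus an intercept) or `d + 1` in
#' full mode. The total is the interpretability proxy MC.
#'
#' @param active `K x d` logical activation mask; every rule must have at
#'   least one active feature.
#' @param mode `"reduced"` or `"full"` consequent dimensionality.
#' @param d Total feature count; defaults to `ncol(active)`.
#' @return An object of class `tsk_complexity`: data frame `per_rule` with
#'   columns `rule`, `n_active`, `antecedent_params`, `consequent_params`,
#'   and the `total` MC.
#' @examples
#' mask <- matrix(TRUE, 15, 15)
#' model_complexity(mask, mode = "reduced")$total  # 690
#' @export
model_complexity <- function(active, mode = c("reduced", "full"),
                             d = ncol(active)) {
  mode <- match.arg(mode)
  active <- as.matrix(active)
  if (!is.logical(active)) storage.mode(active) <- "logical"
  d_k <- rowSums(active)
  if (any(d_k < 1L)) stop("every rule must have at least one active feature")
  ante <- 2L * d_k
  cons <- if (mode == "reduced") d_k + 1L else rep(d + 1L, nrow(active))
  structure(list(per_rule = data.frame(rule = seq_len(nrow(active)),
                                       n_active = as.integer(d_k),
                                       antecedent_params = as.integer(ante),
                                       consequent_params = as.integer(cons)),
                 mode = mode, total = as.integer(sum(ante) + sum(cons))),
            class = "tsk_complexity")
}

#' @export
print.tsk_complexity <- function(x, ...) {
  cat(sprintf("<tsk_complexity> mode = %s, total MC = %d\n", x$mode, x$total))
  print(x$per_rule, row.names = FALSE)
  invisible(x)
}
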