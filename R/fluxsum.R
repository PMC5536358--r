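# Metabolite flux sums (compartment-summed production rates), fold changes,
# change signs, and sign-concordance similarity against reference tables.

EPS_RATE <- 1e-9       # production-rate floor
EPS_SIGN <- 1e-6       # |lfc| below this is "no change"

#' Compartment-summed production rate of a metabolite (flux sum)
#'
#' For every non-boundary compartment instance of the metabolite, sums the
#' forward fluxes of reactions producing it plus the backward fluxes of
#' reactions consuming it in the forward direction — a one-directional
#' flux-sum, not the (identically zero) net balance. Boundary-compartment
#' instances are excluded: the quantity stands in for an intracellular pool.
#'
#' @param system an `irreversible_system`
#' @param state an optimal `flux_state`
#' @param base_id compartment-free metabolite identifier
#' @return non-negative production rate
#' @export
production_rate <- function(system, state, base_id) {
  stopifnot(identical(state$status, "optimal"))
  mets <- system$model$metabolites
  rows <- which(mets$base_id == base_id)
  if (length(rows) == 0L) stop("unknown metabolite: ", base_id)
  rows <- rows[mets$compartment[rows] != system$model$boundary_compartment]
  if (length(rows) == 0L)
    stop("metabolite '", base_id, "' exists only in the boundary compartment; ",
         "use the exchange flux of its exchange reaction instead")
  # in split-column coordinates every positive coefficient times its column
  # flux is a production term (backward columns carry negated stoichiometry)
  Ssub <- system$S[rows, , drop = FALSE]
  pos <- pmax(as.matrix(Ssub), 0)
  max(sum(pos %*% state$v), 0)
}

#' Production rates for many metabolites at once
#'
#' @inheritParams production_rate
#' @param base_ids character vector of compartment-free ids
#' @return named numeric vector
#' @export
production_rates <- function(system, state, base_ids) {
  stats::setNames(vapply(base_ids, function(b)
    production_rate(system, state, b), numeric(1)), base_ids)
}

#' Fold change of a production rate
#'
#' Ratio of deficient to normal production rate with an epsilon policy for
#' vanishing rates: both rates at or below `eps` is "no change" (undefined
#' fold change); exactly one at or below `eps` floors that side at `eps`
#' and flags the result "saturated".
#'
#' @param r_def,r_norm non-negative production rates
#' @param eps rate floor (default `1e-9`)
#' @return list with `fc`, `lfc` (log2 of `fc`; both `NA` for no change)
#'   and `status` in `"ok"`, `"no_change"`, `"saturated"`
#' @export
fold_change <- function(r_def, r_norm, eps = EPS_RATE) {
  if (r_def < 0 || r_norm < 0)
    stop("production rates must be non-negative")
  if (r_def <= eps && r_norm <= eps)
    return(list(fc = NA_real_, lfc = NA_real_, status = "no_change"))
  status <- if (r_def <= eps || r_norm <= eps) "saturated" else "ok"
  fc <- max(r_def, eps) / max(r_norm, eps)
  list(fc = fc, lfc = log2(fc), status = status)
}

#' Sign of a log fold change
#'
#' @param lfc log2 fold change (`NA` for undefined)
#' @param eps_sign no-change band on `|lfc|` (default `1e-6`)
#' @return `+1`, `-1` or `0`
#' @export
sign_of_change <- function(lfc, eps_sign = EPS_SIGN) {
  if (is.na(lfc) || abs(lfc) < eps_sign) 0 else as.integer(sign(lfc))
}

#' Production profile between two flux states
#'
#' @param system an `irreversible_system`
#' @param normal,deficient optimal `flux_state`s
#' @param base_ids metabolites to profile
#' @param eps,eps_sign epsilon policies of [fold_change()] / [sign_of_change()]
#' @return data.frame (`metabolite`, `r_normal`, `r_deficient`, `fc`, `lfc`,
#'   `status`, `pred_sign`)
#' @export
production_profile <- function(system, normal, deficient, base_ids,
                               eps = EPS_RATE, eps_sign = EPS_SIGN) {
  rn <- production_rates(system, normal, base_ids)
  rd <- production_rates(system, deficient, base_ids)
  rows <- lapply(base_ids, function(b) {
    f <- fold_change(rd[[b]], rn[[b]], eps)
    data.frame(metabolite = b, r_normal = rn[[b]], r_deficient = rd[[b]],
               fc = f$fc, lfc = f$lfc, status = f$status,
               pred_sign = sign_of_change(f$lfc, eps_sign),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reference sign table
#'
#' @param label short label, e.g. `"experiment"` or `"warburg"`
#' @param signs named vector of `+1`/`-1`/`0` keyed by metabolite id
#' @return object of class `sign_table` with `n_total = length(signs)`
#' @export
sign_table <- function(label, signs) {
  if (length(signs) == 0L) stop("empty sign table")
  stopifnot(!is.null(names(signs)), all(nzchar(names(signs))))
  if (anyDuplicated(names(signs)))
    stop("duplicate metabolite(s) in sign table: ",
         paste(unique(names(signs)[duplicated(names(signs))]), collapse = ", "))
  s <- as.integer(signs)
  if (!all(s %in% c(-1L, 0L, 1L)))
    stop("signs must be -1, 0 or +1")
  structure(list(label = label,
                 signs = stats::setNames(s, names(signs)),
                 n_total = length(s)), class = "sign_table")
}

#' @export
print.sign_table <- function(x, ...) {
  cat("sign_table '", x$label, "': ", x$n_total, " metabolites (",
      sum(x$signs > 0), " up, ", sum(x$signs < 0), " down, ",
      sum(x$signs == 0), " unchanged)\n", sep = "")
  invisible(x)
}

parse_sign <- function(txt) {
  txt <- trimws(txt)
  up <- c("↑", "+1", "1", "+", "up", "increase")
  dn <- c("↓", "-1", "-", "down", "decrease")
  nc <- c("0", "nc", "no_change", "none", "~", "=")
  out <- ifelse(txt %in% up, 1L, ifelse(txt %in% dn, -1L,
                ifelse(txt %in% nc, 0L, NA_integer_)))
  if (anyNA(out)) stop("unparseable sign value(s): ",
                       paste(unique(txt[is.na(out)]), collapse = ", "))
  out
}

#' Read a sign table from TSV
#'
#' Expects columns `metabolite_id` and `sign`; arrows, `+1`/`-1`/`0` and
#' up/down words are all accepted. An optional `source_label` column (first
#' value) names the table; otherwise the file stem is used.
#'
#' @param path TSV file path
#' @param label override the table label
#' @return a `sign_table`
#' @export
read_sign_table <- function(path, label = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "sign") %in% names(d)))
  if (is.null(label))
    label <- if ("source_label" %in% names(d)) d$source_label[1]
             else sub("\\.[^.]*$", "", basename(path))
  sign_table(label, stats::setNames(parse_sign(d$sign), d$metabolite_id))
}

#' Sign-concordance similarity ratio
#'
#' Fraction of reference metabolites whose predicted change sign matches
#' the reference sign. Under `policy = "all"` the denominator is the full
#' reference size and a 0/0 match counts as agreement; under
#' `policy = "defined_only"` only entries where both signs are non-zero
#' enter numerator and denominator. Metabolites without a prediction count
#' as sign 0 (`missing = "zero"`) or are dropped from the denominator with
#' a warning (`missing = "drop"`).
#'
#' @param pred named vector of predicted signs (`+1`/`-1`/`0`)
#' @param ref a `sign_table`
#' @param policy `"all"` (default) or `"defined_only"`
#' @param missing `"zero"` (default) or `"drop"`
#' @return list (`label`, `mu` named 0/1 indicator, `sr`, `n_agree`,
#'   `denominator`)
#' @export
similarity_ratio <- function(pred, ref, policy = c("all", "defined_only"),
                             missing = c("zero", "drop")) {
  policy <- match.arg(policy); missing <- match.arg(missing)
  stopifnot(inherits(ref, "sign_table"))
  mets <- names(ref$signs)
  absent <- setdiff(mets, names(pred))
  if (missing == "drop" && length(absent)) {
    warning("dropping ", length(absent),
            " reference metabolite(s) without predictions: ",
            paste(absent, collapse = ", "))
    mets <- setdiff(mets, absent)
    if (length(mets) == 0L) stop("no reference metabolites left to score")
  }
  p <- stats::setNames(rep(0L, length(mets)), mets)
  have <- intersect(mets, names(pred))
  p[have] <- as.integer(pred[have])
  r <- ref$signs[mets]
  if (policy == "defined_only") {
    use <- p != 0L & r != 0L
    if (!any(use)) stop("no jointly non-zero entries under policy 'defined_only'")
    mu <- stats::setNames(as.integer(p[use] == r[use]), mets[use])
    denom <- sum(use)
  } else {
    mu <- stats::setNames(as.integer(p == r), mets)
    denom <- length(mets)
  }
  list(label = ref$label, mu = mu, sr = sum(mu) / denom,
       n_agree = sum(mu), denominator = denom)
}

#' Rank genes by similarity ratio
#'
#' @param reports list of per-gene report rows; each must carry `gene` and
#'   an `sr` named list/vector containing `key`
#' @param key reference label to rank on
#' @return data.frame sorted by descending similarity ratio, ties broken by
#'   gene id (lexicographic)
#' @export
rank_genes <- function(reports, key) {
  rows <- lapply(reports, function(r) {
    if (!key %in% names(r$sr)) stop("report for gene ", r$gene,
                                    " lacks reference '", key, "'")
    data.frame(gene = r$gene, sr = unname(r$sr[[key]]),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  d[order(-d$sr, d$gene), , drop = FALSE]
}
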