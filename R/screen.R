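# Orchestration: normal state, per-gene dysregulation, flux sums, similarity
# ratios, ranked screen reports. These functions are the package's driving
# interface; see the vignette for a worked screen.

#' Screen configuration
#'
#' @param default_delta regulation strength applied when a gene row does not
#'   override it (default 1, i.e. full overexpression)
#' @param policy similarity denominator policy, `"all"` or `"defined_only"`
#' @param missing how to treat reference metabolites absent from the model,
#'   `"drop"` (default: removed from the denominator with a warning) or
#'   `"zero"`
#' @param eps production-rate floor
#' @param eps_sign no-change band on |log2 fold change|
#' @param delta_tol bisection tolerance of the maximal-strength fallback
#' @return object of class `screen_config`
#' @export
screen_config <- function(default_delta = 1, policy = "all",
                          missing = "drop", eps = EPS_RATE,
                          eps_sign = EPS_SIGN, delta_tol = 0.005) {
  stopifnot(default_delta >= 0, default_delta <= 1)
  structure(list(default_delta = default_delta, policy = policy,
                 missing = missing, eps = eps, eps_sign = eps_sign,
                 delta_tol = delta_tol), class = "screen_config")
}

#' Solve and cache the normal state
#'
#' Runs the two-stage normal-state problem and computes flux ranges for the
#' columns of every reaction mapped by the configured genes. The returned
#' cache is treated as immutable by the per-gene runs.
#'
#' @param model a `metabolic_model` (medium already applied)
#' @param genes character vector of gene ids the screen will regulate
#'   (default: all genes in the model)
#' @param range_mode `"free"` (default) or `"objective_fixed"`
#' @return list (`model`, `system`, `z_star`, `normal` flux_state, `ranges`)
#' @export
run_normal_state <- function(model, genes = model_genes(model),
                             range_mode = "free") {
  system <- split_reversible(model)
  ts <- solve_two_stage(system)
  if (!identical(ts$state$status, "optimal"))
    stop("normal state ", ts$state$status,
         "; check the medium and exchange bounds")
  if (ts$z_star <= ZERO_FLUX_TOL)
    stop("normal state infeasible or zero: objective optimum is 0; ",
         "the medium admits no objective flux")
  cols <- unique(unlist(lapply(genes, function(g)
    lapply(gene_to_reactions(model, g), function(rid)
      names(reaction_columns(system, rid))))))
  ranges <- if (length(cols))
    flux_range(system, cols, mode = range_mode,
               z_star = if (range_mode == "objective_fixed") ts$z_star,
               basal_state = ts$state)
  else NULL
  list(model = model, system = system, z_star = ts$z_star,
       normal = ts$state, ranges = ranges, genes = genes)
}

#' Run one gene's dysregulation
#'
#' Applies the gene's regulation mode and strength, with a
#' maximal-feasible-strength fallback when the requested strength is
#' infeasible, solves the deficient two-stage problem, and profiles
#' production-rate fold changes and sign concordance against each reference
#' table.
#'
#' @param cache output of [run_normal_state()]
#' @param gene gene id
#' @param mode regulation mode (default `"up"`)
#' @param delta regulation strength (default from `config`)
#' @param sign_tables list of `sign_table` references
#' @param config a `screen_config`
#' @param reactions optional explicit reaction override
#' @return list (`gene`, `mode`, `delta_used`, `capped`, `feasible`,
#'   `z_deficient`, `deficient`, `profile`, `sr`, `reports`)
#' @export
run_gene <- function(cache, gene, mode = "up", delta = NULL,
                     sign_tables = list(), config = screen_config(),
                     reactions = NULL) {
  delta <- delta %||% config$default_delta
  capped <- FALSE
  if (mode == "knockout") {
    spec <- build_regulation(cache$model, cache$system, gene, "knockout",
                             reactions = reactions)
  } else {
    spec <- build_regulation(cache$model, cache$system, gene, mode, delta,
                             cache$normal, cache$ranges, reactions = reactions)
  }
  fixed <- apply_regulation(cache$system, spec)
  ts <- solve_two_stage(cache$system, fixed)
  if (!identical(ts$state$status, "optimal") && mode != "knockout") {
    mf <- max_feasible_delta(cache$model, cache$system, gene, mode,
                             cache$normal, cache$ranges,
                             tol = config$delta_tol, reactions = reactions)
    capped <- TRUE
    delta <- mf$delta_star
    spec <- mf$spec
    fixed <- apply_regulation(cache$system, spec)
    ts <- solve_two_stage(cache$system, fixed)
  }
  feasible <- identical(ts$state$status, "optimal")
  profile <- NULL; sr <- list(); reports <- list()
  if (feasible && length(sign_tables)) {
    mets <- unique(unlist(lapply(sign_tables, function(tb) names(tb$signs))))
    modeled <- intersect(
      mets, cache$model$metabolites$base_id[
        cache$model$metabolites$compartment != cache$model$boundary_compartment])
    profile <- production_profile(cache$system, cache$normal, ts$state,
                                  modeled, config$eps, config$eps_sign)
    pred <- stats::setNames(profile$pred_sign, profile$metabolite)
    for (tb in sign_tables) {
      rep_k <- similarity_ratio(pred, tb, policy = config$policy,
                                missing = config$missing)
      sr[[tb$label]] <- rep_k$sr
      reports[[tb$label]] <- rep_k
    }
  }
  list(gene = gene, mode = mode, delta_used = delta, capped = capped,
       feasible = feasible,
       z_deficient = if (feasible) ts$z_star else NA_real_,
       deficient = ts$state, profile = profile, sr = sr, reports = reports)
}

#' Run the full dysregulation screen
#'
#' Iterates [run_gene()] over a gene table, isolating per-gene failures
#' (unmapped genes or solver failures are recorded and the screen
#' continues), and assembles the ranked similarity table.
#'
#' @param model a `metabolic_model` (medium already applied)
#' @param gene_table data.frame with columns `gene`, optionally `mode`
#'   (default `"up"`) and `delta` (default from `config`); or a character
#'   vector of genes
#' @param sign_tables list of `sign_table` references
#' @param config a `screen_config`
#' @return object of class `screen_result`: `ranking` (data.frame with one
#'   row per gene: `gene`, `mode`, `delta_used`, `capped`, `feasible`,
#'   `z_deficient`, one `sr_<label>` column per reference, `note`),
#'   `details` (per-gene [run_gene()] outputs), `normal` (the cache), and
#'   `manifest`
#' @export
run_screen <- function(model, gene_table, sign_tables = list(),
                       config = screen_config()) {
  if (is.character(gene_table))
    gene_table <- data.frame(gene = gene_table, stringsAsFactors = FALSE)
  stopifnot("gene" %in% names(gene_table))
  if (nrow(gene_table) > 0L) {
    if (is.null(gene_table$mode)) gene_table$mode <- "up"
    if (is.null(gene_table$delta)) gene_table$delta <- NA_real_
  }
  if (nrow(gene_table) == 0L) {
    warning("screen called with zero genes; returning empty report")
    return(structure(list(
      ranking = data.frame(gene = character(0)), details = list(),
      normal = NULL,
      manifest = screen_manifest(model, gene_table, sign_tables, config)),
      class = "screen_result"))
  }
  mapped <- vapply(gene_table$gene, function(g)
    length(gene_to_reactions(model, g)) > 0L, logical(1))
  cache <- run_normal_state(model, genes = gene_table$gene[mapped])

  labels <- vapply(sign_tables, function(tb) tb$label, character(1))
  details <- list()
  rows <- list()
  for (k in seq_len(nrow(gene_table))) {
    g <- gene_table$gene[k]
    row <- data.frame(gene = g, mode = gene_table$mode[k],
                      delta_used = NA_real_, capped = FALSE,
                      feasible = FALSE, z_deficient = NA_real_,
                      stringsAsFactors = FALSE)
    for (lb in labels) row[[paste0("sr_", lb)]] <- NA_real_
    row$note <- ""
    if (!mapped[k]) {
      row$note <- "unmapped"
    } else {
      res <- tryCatch(
        run_gene(cache, g, mode = gene_table$mode[k],
                 delta = if (is.na(gene_table$delta[k])) NULL
                         else gene_table$delta[k],
                 sign_tables = sign_tables, config = config),
        error = function(e) e)
      if (inherits(res, "error")) {
        row$note <- paste0("error: ", conditionMessage(res))
      } else {
        details[[g]] <- res
        row$delta_used <- res$delta_used
        row$capped <- res$capped
        row$feasible <- res$feasible
        row$z_deficient <- res$z_deficient
        for (lb in names(res$sr)) row[[paste0("sr_", lb)]] <- res$sr[[lb]]
        if (res$capped) row$note <- "partially regulable (delta capped)"
        if (!res$feasible) row$note <- "infeasible"
      }
    }
    rows[[k]] <- row
  }
  ranking <- do.call(rbind, rows)
  if (length(labels)) {
    key <- paste0("sr_", labels[1])
    ord <- order(-ifelse(is.na(ranking[[key]]), -Inf, ranking[[key]]),
                 ranking$gene)
    ranking <- ranking[ord, , drop = FALSE]
  } else ranking <- ranking[order(ranking$gene), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, details = details, normal = cache,
                 manifest = screen_manifest(model, gene_table, sign_tables,
                                            config)),
            class = "screen_result")
}

screen_manifest <- function(model, gene_table, sign_tables, config) {
  list(package = "hepaflux",
       version = as.character(utils::packageVersion("hepaflux")),
       model = list(metabolites = nrow(model$metabolites),
                    reactions = nrow(model$reactions),
                    compartments = model$compartments,
                    objective = model$objective),
       genes = gene_table,
       references = vapply(sign_tables, function(tb) tb$label, character(1)),
       config = unclass(config))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result over ", nrow(x$ranking), " gene(s)\n", sep = "")
  print(x$ranking, digits = 4)
  invisible(x)
}

#' Write screen reports to a directory
#'
#' Emits `ranking.tsv` (the ranked gene table), one
#' `arrows_<gene>.tsv` per-gene metabolite table mirroring an arrow-table
#' layout (metabolite, normal/deficient rates, fold change, sign), and
#' `manifest.json`. Output is deterministic for identical inputs.
#'
#' @param result a `screen_result`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_screen_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  rp <- file.path(dir, "ranking.tsv")
  rk <- result$ranking
  num <- vapply(rk, is.numeric, logical(1))
  rk[num] <- lapply(rk[num], function(col) ifelse(is.na(col), NA,
                                                  sprintf("%.6g", col)))
  utils::write.table(rk, rp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, rp)
  for (g in names(result$details)) {
    d <- result$details[[g]]
    if (is.null(d$profile)) next
    ap <- file.path(dir, paste0("arrows_", g, ".tsv"))
    pr <- d$profile
    pr$arrow <- ifelse(pr$pred_sign > 0, "up",
                       ifelse(pr$pred_sign < 0, "down", "-"))
    pr[c("r_normal", "r_deficient", "fc", "lfc")] <-
      lapply(pr[c("r_normal", "r_deficient", "fc", "lfc")],
             function(col) ifelse(is.na(col), NA, sprintf("%.6g", col)))
    utils::write.table(pr, ap, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, ap)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(result$manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}
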