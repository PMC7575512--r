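# Dataset assembly (CSV + newick), report rendering and JSON round-trip.

#' Load a species x trait table from CSV
#'
#' Reads a CSV with a species column and numeric trait columns, keeps the
#' requested columns, drops species with any missing value among them
#' (complete cases; a message reports how many were dropped) and, by
#' default, log10-transforms the values — comparative length data are
#' analysed on the log10 scale so that rates are proportional changes.
#'
#' Trait lengths compiled from the literature may be reported in different
#' units (e.g. micrometres vs millimetres); the package never converts
#' units, because log10 of mixed units would corrupt the rates. When `units`
#' is supplied it must declare one common unit for all requested columns,
#' and mixed declarations abort.
#'
#' @param path CSV file path.
#' @param columns Character vector of trait columns to keep (default: all
#'   columns except the species column).
#' @param species_col Name of the species column (default `"species"`).
#' @param log10 Logical; transform values by log10 (default `TRUE`).
#'   Non-positive values are then an error.
#' @param units Optional named character vector declaring the unit of each
#'   requested column.
#' @return Numeric matrix with canonicalised species rownames.
#' @export
load_traits <- function(path, columns = NULL, species_col = "species",
                        log10 = TRUE, units = NULL) {
  if (!file.exists(path)) stop_input("trait file not found: %s", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!species_col %in% names(raw))
    stop_input("species column '%s' not found (columns: %s)", species_col,
               paste(names(raw), collapse = ", "))
  avail <- setdiff(names(raw), species_col)
  if (is.null(columns)) columns <- avail
  unknown <- setdiff(columns, avail)
  if (length(unknown))
    stop_input("unknown trait column(s) %s; available: %s",
               paste(unknown, collapse = ", "), paste(avail, collapse = ", "))
  if (!is.null(units)) {
    u <- units[columns]
    if (anyNA(u)) stop_input("units declared but missing for column(s): %s",
                             paste(columns[is.na(u)], collapse = ", "))
    if (length(unique(u)) > 1)
      stop_input("mixed units across traits (%s); convert before loading",
                 paste(paste0(columns, "=", u), collapse = ", "))
  }

  species <- canonical_labels(raw[[species_col]])
  if (anyDuplicated(species))
    stop_input("duplicate species row(s): %s",
               paste(unique(species[duplicated(species)]), collapse = ", "))
  X <- matrix(NA_real_, nrow(raw), length(columns),
              dimnames = list(species, columns))
  for (cl in columns) {
    v <- raw[[cl]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "NA")
    if (length(bad))
      stop_input("non-numeric value '%s' in column '%s', row %d",
                 v[bad[1]], cl, bad[1])
    X[, cl] <- num
  }
  keep <- complete.cases(X)
  if (sum(keep) == 0) stop_input("no species with complete data for: %s",
                                 paste(columns, collapse = ", "))
  if (any(!keep))
    message(sprintf("dropped %d species with missing values: %s",
                    sum(!keep), paste(species[!keep], collapse = ", ")))
  X <- X[keep, , drop = FALSE]
  if (log10) {
    if (any(X <= 0)) {
      idx <- which(X <= 0, arr.ind = TRUE)[1, ]
      stop_input("non-positive value (%g) for species '%s', trait '%s' cannot be log10-transformed",
                 X[idx[1], idx[2]], rownames(X)[idx[1]], colnames(X)[idx[2]])
    }
    X <- log10(X)
  }
  X
}

#' Assemble an aligned analysis dataset from a tree and a trait table
#'
#' Matches species between the tree and the trait table (exact match after
#' trimming whitespace and unifying underscores/spaces), reports what is
#' dropped on either side, prunes the tree to the intersection, orders the
#' trait rows canonically by tree traversal order, and builds the
#' phylogenetic covariance matrix. Permuting the CSV row order therefore
#' cannot change any downstream result.
#'
#' @param tree A `phylo` object or path to a newick file.
#' @param traits A numeric matrix with species rownames (e.g. from
#'   [load_traits()]) or a path to a CSV file.
#' @param columns,species_col,log10,units Passed to [load_traits()] when
#'   `traits` is a path. An in-memory trait matrix is taken as already being
#'   on the analysis scale: no transformation is applied to it.
#' @param strict Passed to [read_newick()] when `tree` is a path.
#' @return List with `X` (aligned trait matrix), `C` (phylogenetic
#'   covariance), `tree` (pruned), `dropped_tips`, `dropped_species`.
#' @export
assemble_dataset <- function(tree, traits, columns = NULL,
                             species_col = "species", log10 = TRUE,
                             units = NULL, strict = FALSE) {
  if (is.character(tree)) tree <- read_newick(file = tree, strict = strict)
  validate_phylogeny(tree)
  if (is.character(traits))
    traits <- load_traits(traits, columns = columns, species_col = species_col,
                          log10 = log10, units = units)
  X <- as.matrix(traits)
  if (is.null(rownames(X))) stop_input("trait table must have species rownames")
  rownames(X) <- canonical_labels(rownames(X))
  tree$tip.label <- canonical_labels(tree$tip.label)
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]

  common <- intersect(tree$tip.label, rownames(X))
  if (length(common) < 2) {
    near <- paste0("tree: ", paste(head(tree$tip.label, 5), collapse = ", "),
                   " | traits: ", paste(head(rownames(X), 5), collapse = ", "))
    stop_input("fewer than 2 species shared between tree and trait table (%s)", near)
  }
  dropped_tips <- setdiff(tree$tip.label, common)
  dropped_species <- setdiff(rownames(X), common)
  if (length(dropped_tips))
    message(sprintf("dropped %d tree tip(s) without trait data: %s",
                    length(dropped_tips), paste(dropped_tips, collapse = ", ")))
  if (length(dropped_species))
    message(sprintf("dropped %d trait row(s) not in tree: %s",
                    length(dropped_species), paste(dropped_species, collapse = ", ")))
  tree <- prune_to_taxa(tree, common)
  ord <- tree$tip.label
  X <- X[ord, , drop = FALSE]
  C <- phylo_covariance(tree, order = ord)
  list(X = X, C = C, tree = tree,
       dropped_tips = dropped_tips, dropped_species = dropped_species)
}

#' Render a rate comparison as text, JSON or TSV
#'
#' The text layout mirrors the standard presentation of multi-trait rate
#' comparisons: lower-triangular observed rate matrix with the common-model
#' values in brackets (rates on the diagonal), then n, LogL_obs
#' (LogL_common), LRT with df, p (two decimals, `<0.001` below that) and
#' AIC_obs (AIC_common). JSON carries full precision and round-trips through
#' [parse_report_json()]; TSV is a one-row machine-readable summary.
#'
#' @param result A `rate_comparison` or `rate_posthoc` object.
#' @param format `"text"`, `"json"` or `"tsv"`.
#' @param digits Decimal places for the text rendering (default 2).
#' @return Character vector of lines (`text`, `tsv`) or a JSON string.
#' @export
render_report <- function(result, format = c("text", "json", "tsv"), digits = 2) {
  format <- match.arg(format)
  if (inherits(result, "rate_posthoc")) {
    if (format == "json")
      return(as.character(jsonlite::toJSON(list(
        kind = "rate_posthoc", alpha = result$alpha, adjust = result$adjust,
        n = result$n, p = result$p, rates = as.list(result$rates),
        letters = as.list(result$letters), table = result$table),
        auto_unbox = TRUE, digits = NA)))
    if (format == "tsv") {
      tab <- result$table
      return(c(paste(names(tab), collapse = "\t"),
               apply(tab, 1, paste, collapse = "\t")))
    }
    return(utils::capture.output(print(result, digits = digits)))
  }
  if (!inherits(result, "rate_comparison"))
    stop_input("cannot render object of class '%s'", paste(class(result), collapse = "/"))

  x <- result
  if (format == "json") {
    payload <- list(
      kind = "rate_comparison", n = x$n, p = x$p,
      traits = colnames(x$observed$R), common_model = x$common_model,
      observed = list(R = x$observed$R, mu = as.list(x$observed$mu),
                      logL = x$observed$logL, k = x$observed$k,
                      AIC = x$observed$AIC),
      common = list(R = x$common$R, mu = as.list(x$common$mu),
                    logL = x$common$logL, k = x$common$k, AIC = x$common$AIC,
                    sigma2 = x$common$sigma2_common),
      LRT = x$LRT, df = x$df, p_value = x$p_value,
      rate_ratios = x$rate_ratios)
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)))
  }
  if (format == "tsv") {
    hdr <- c("n", "p", "logL_obs", "logL_common", "LRT", "df", "p_value",
             "AIC_obs", "AIC_common", "sigma2_common")
    val <- c(x$n, x$p, x$observed$logL, x$common$logL, x$LRT, x$df,
             x$p_value, x$observed$AIC, x$common$AIC, x$common$sigma2_common)
    return(c(paste(hdr, collapse = "\t"), paste(val, collapse = "\t")))
  }

  traits <- colnames(x$observed$R)
  cell <- function(i, j)
    sprintf("%s (%s)", fmt_num(x$observed$R[i, j], digits),
            fmt_num(x$common$R[i, j], digits))
  body <- vapply(seq_along(traits), function(i)
    paste(vapply(seq_len(i), function(j) sprintf("%-14s", cell(i, j)),
                 character(1)), collapse = ""), character(1))
  c(sprintf("Evolutionary rate comparison: observed vs common-rate Brownian model"),
    sprintf("n = %d species, p = %d traits (common model: %s)", x$n, x$p, x$common_model),
    "",
    "observed rate matrix, common-model values in brackets (diagonal = sigma^2):",
    paste0("  ", format(traits, width = 20), body),
    "",
    sprintf("LogL_obs (LogL_common): %s (%s)", fmt_num(x$observed$logL, digits),
            fmt_num(x$common$logL, digits)),
    sprintf("LRT (df = %d): %s", x$df, fmt_num(x$LRT, digits)),
    sprintf("p: %s", format_p(x$p_value, digits)),
    sprintf("AIC_obs (AIC_common): %s (%s)", fmt_num(x$observed$AIC, digits),
            fmt_num(x$common$AIC, digits)))
}

#' Reload a rate comparison from its JSON report
#'
#' Inverse of `render_report(x, "json")`: reconstructs a `rate_comparison`
#' whose numeric content matches the original at full precision.
#'
#' @param json A JSON string produced by [render_report()].
#' @return A `rate_comparison` object.
#' @export
parse_report_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (is.null(obj$kind) || obj$kind != "rate_comparison")
    stop_input("JSON does not encode a rate_comparison report")
  traits <- obj$traits
  as_mat <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(traits, traits)
    m
  }
  mk_fit <- function(f, model, sigma2 = NULL)
    new_bm_fit(model, as_mat(f$R), setNames(unlist(f$mu), traits),
               f$logL, f$k, obj$n, sigma2 = sigma2)
  out <- list(observed = mk_fit(obj$observed, "observed"),
              common = mk_fit(obj$common, "common", sigma2 = obj$common$sigma2),
              LRT = obj$LRT, df = as.integer(obj$df), p_value = obj$p_value,
              rate_ratios = as_mat(obj$rate_ratios),
              n = as.integer(obj$n), p = as.integer(obj$p),
              common_model = obj$common_model)
  class(out) <- "rate_comparison"
  out
}
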