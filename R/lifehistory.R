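#' Harmonize species names against a synonym table
#'
#' Maps raw binomials to accepted binomials and higher taxonomy using a
#' local synonym table (columns: raw_name, accepted, class, order, family).
#' Unmatched names are reported in the `unmatched` attribute, not silently
#' dropped; a raw name mapping to two accepted names is an error.
#'
#' @param records tibble with a `species` column of raw binomials.
#' @param synonyms the synonym table.
#' @return `records` with `species` replaced by the accepted binomial and
#'   class/order/family attached; unmatched records removed and listed in
#'   the `unmatched` attribute.
#' @export
harmonize_taxonomy <- function(records, synonyms) {
  stopifnot(all(c("raw_name", "accepted", "class", "order", "family") %in%
                  names(synonyms)))
  dup <- dplyr::summarise(dplyr::group_by(synonyms, .data$raw_name),
                          n = dplyr::n_distinct(.data$accepted),
                          .groups = "drop")
  if (any(dup$n > 1)) {
    abort(paste("conflicting synonym mappings for:",
                paste(dup$raw_name[dup$n > 1], collapse = ", ")))
  }
  synonyms <- dplyr::distinct(synonyms, .data$raw_name, .keep_all = TRUE)
  matched <- records$species %in% synonyms$raw_name
  unmatched <- sort(unique(records$species[!matched]))
  out <- dplyr::inner_join(
    dplyr::rename(records, raw_name = "species"),
    synonyms[c("raw_name", "accepted", "class", "order", "family")],
    by = "raw_name")
  out <- dplyr::rename(out, species = "accepted")
  out$raw_name <- NULL
  out <- dplyr::relocate(out, "species")
  attr(out, "unmatched") <- unmatched
  out
}

#' Aggregate repeated trait records per species
#'
#' When several estimates of a trait exist for one species (within or
#' across source datasets), values are log-transformed, averaged, and
#' back-transformed (a geometric mean). Missing traits stay missing.
#'
#' @param records tibble: species, any of longevity, maturity,
#'   reproductive_events, offspring, body_mass, plus optional taxonomy
#'   columns (class, order, family) carried through.
#' @return tibble with one row per species.
#' @export
aggregate_traits <- function(records) {
  traits <- intersect(c("longevity", "maturity", "reproductive_events",
                        "offspring", "body_mass"), names(records))
  if (!length(traits)) abort("no trait columns found")
  for (tr in traits) {
    if (any(records[[tr]] <= 0, na.rm = TRUE)) {
      abort(sprintf("non-positive values in trait `%s`", tr))
    }
  }
  tax <- intersect(c("class", "order", "family"), names(records))
  dplyr::summarise(
    dplyr::group_by(records, .data$species),
    dplyr::across(dplyr::all_of(traits), geometric_mean),
    dplyr::across(dplyr::all_of(tax), ~ .x[1]),
    .groups = "drop")
}

#' Phylogenetic eigenvectors
#'
#' Principal-coordinate decomposition of the pairwise patristic distance
#' matrix of a phylogeny; the leading eigenvectors are continuous
#' predictors encoding relatedness for trait imputation. Species absent
#' from the tree receive `NA` eigenvectors and are flagged.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param species character vector of species to return rows for; defaults
#'   to the tree's tips.
#' @param n number of eigenvectors (default 10).
#' @return tibble: species, in_tree (logical), ev1..evn.
#' @export
phylo_eigenvectors <- function(tree, species = NULL, n = 10L) {
  if (!inherits(tree, "phylo")) abort("tree must be an ape phylo object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  if (ntip < n + 1L) {
    abort(sprintf("need at least %d species on the tree for %d eigenvectors",
                  n + 1L, n))
  }
  species <- species %||% tree$tip.label
  D <- ape::cophenetic.phylo(tree)
  # Gower double-centering of -D^2/2, then eigendecomposition
  A <- -0.5 * D^2
  ctr <- diag(ntip) - matrix(1 / ntip, ntip, ntip)
  G <- ctr %*% A %*% ctr
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values) * 1e-10)
  take <- head(pos, n)
  vec <- eig$vectors[, take, drop = FALSE] %*%
    diag(sqrt(eig$values[take]), length(take))
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(vec))) {
    if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
  }
  colnames(vec) <- paste0("ev", seq_len(ncol(vec)))
  rownames(vec) <- rownames(D)
  idx <- match(species, rownames(vec))
  out <- tibble::as_tibble(vec[ifelse(is.na(idx), 1L, idx), , drop = FALSE])
  out[is.na(idx), ] <- NA_real_
  dplyr::bind_cols(tibble::tibble(species = species,
                                  in_tree = !is.na(idx)), out)
}

# one random-forest regression/classification fill of a single column
rf_fill <- function(y, X, miss, ntree) {
  fit <- randomForest::randomForest(x = X[!miss, , drop = FALSE],
                                    y = y[!miss], ntree = ntree)
  oob <- if (is.factor(y)) mean(fit$err.rate[ntree, "OOB"])
         else fit$mse[ntree] / max(var(y[!miss]), .Machine$double.eps)
  list(pred = predict(fit, X[miss, , drop = FALSE]), oob = oob)
}

#' Impute missing traits with iterative random forests
#'
#' Missing entries are initialized with column medians and then refilled
#' by per-trait random forests (predictors: the other traits, the leading
#' phylogenetic eigenvectors, and class/order/family factors), visiting
#' traits in order of increasing missingness and iterating until the
#' total out-of-bag error stops decreasing or `max_iter` is reached.
#' Observed values are never altered; traits are modelled on the log
#' scale.
#'
#' @param traits one-row-per-species tibble with the five trait columns
#'   and class/order/family.
#' @param eigenvectors output of [phylo_eigenvectors()] (optional).
#' @param seed integer seed, recorded in the result's attributes.
#' @param ntree trees per forest (default 100).
#' @param max_iter maximum refinement iterations.
#' @return completed tibble plus logical `<trait>_imputed` flag columns;
#'   attributes `seed`, `iterations`, `oob_path`.
#' @export
impute_traits <- function(traits, eigenvectors = NULL, seed = 42L,
                          ntree = 100L, max_iter = 10L) {
  trait_cols <- intersect(c("longevity", "maturity", "reproductive_events",
                            "offspring", "body_mass"), names(traits))
  all_missing <- vapply(traits[trait_cols],
                        function(x) all(is.na(x)), logical(1))
  if (any(all_missing)) {
    abort(paste("trait entirely missing across all species:",
                paste(trait_cols[all_missing], collapse = ", ")))
  }
  miss_mat <- is.na(as.data.frame(traits[trait_cols]))
  out <- traits
  for (tr in trait_cols) out[[paste0(tr, "_imputed")]] <- miss_mat[, tr]
  if (!any(miss_mat)) {
    attr(out, "seed") <- seed
    attr(out, "iterations") <- 0L
    return(out)
  }

  work <- as.data.frame(log(traits[trait_cols]))
  aux <- data.frame(row.names = seq_len(nrow(traits)))
  for (f in intersect(c("class", "order", "family"), names(traits))) {
    v <- factor(traits[[f]])
    if (nlevels(v) > 1L && nlevels(v) <= 53L) aux[[f]] <- v
  }
  if (!is.null(eigenvectors)) {
    ev <- dplyr::left_join(traits["species"], eigenvectors, by = "species")
    for (cl in grep("^ev", names(ev), value = TRUE)) {
      x <- ev[[cl]]
      x[is.na(x)] <- median(x, na.rm = TRUE)
      aux[[cl]] <- x
    }
  }
  for (tr in trait_cols) { # median initialization
    work[[tr]][miss_mat[, tr]] <- median(work[[tr]], na.rm = TRUE)
  }
  order_tr <- trait_cols[order(colSums(miss_mat[, trait_cols, drop = FALSE]))]
  set.seed(seed)
  prev_oob <- Inf
  oob_path <- numeric(0)
  best <- work
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    oob_tot <- 0
    for (tr in order_tr) {
      miss <- miss_mat[, tr]
      if (!any(miss)) next
      X <- cbind(work[setdiff(trait_cols, tr)], aux)
      res <- rf_fill(work[[tr]], X, miss, ntree)
      work[[tr]][miss] <- res$pred
      oob_tot <- oob_tot + res$oob
    }
    oob_path <- c(oob_path, oob_tot)
    if (oob_tot >= prev_oob) break
    prev_oob <- oob_tot
    best <- work
  }
  for (tr in trait_cols) {
    filled <- exp(best[[tr]])
    filled[!miss_mat[, tr]] <- traits[[tr]][!miss_mat[, tr]]
    out[[tr]] <- filled
  }
  attr(out, "seed") <- seed
  attr(out, "iterations") <- iter
  attr(out, "oob_path") <- oob_path
  out
}

# fit log(trait) ~ log(mass) with nested taxonomic random intercepts,
# dropping grouping levels on singular fits
mass_adjust_one <- function(dat, trait) {
  dat$y <- log(dat[[trait]])
  dat$lmass <- log(dat$body_mass)
  groups <- list(c("class", "order", "family"), c("class", "order"),
                 "class", character(0))
  for (g in groups) {
    g <- intersect(g, names(dat))
    g <- g[vapply(dat[g], function(x) length(unique(x)) > 1L, logical(1))]
    if (!length(g)) break
    re <- paste0("(1|", paste(g, collapse = "/"), ")")
    fit <- tryCatch(
      suppressMessages(lme4::lmer(as.formula(paste("y ~ lmass +", re)),
                                  data = dat)),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
      return(list(resid = residuals(fit), grouping = g))
    }
  }
  fit <- lm(y ~ lmass, data = dat)
  list(resid = residuals(fit), grouping = character(0))
}

#' Mass- and kinship-adjusted life-history traits
#'
#' Regresses each log trait (longevity, maturity, reproductive events,
#' offspring) on log body mass with nested taxonomic random intercepts
#' (family within order within class) and returns the conditional
#' residuals: the trait with allometric scaling and group-level kinship
#' effects removed. Singular fits fall back to coarser grouping (logged in
#' the `grouping` attribute).
#'
#' @param traits complete one-row-per-species tibble (five traits +
#'   class/order/family).
#' @return tibble: species plus four residual trait columns; attribute
#'   `grouping` records the random-effect structure used per trait.
#' @export
mass_adjust <- function(traits) {
  need <- c("longevity", "maturity", "reproductive_events", "offspring",
            "body_mass")
  miss <- setdiff(need, names(traits))
  if (length(miss)) {
    abort(paste("missing trait columns:", paste(miss, collapse = ", ")))
  }
  if (anyNA(traits[need])) abort("traits must be complete; impute first")
  out <- tibble::tibble(species = traits$species)
  grouping <- list()
  for (tr in setdiff(need, "body_mass")) {
    res <- mass_adjust_one(as.data.frame(traits), tr)
    out[[tr]] <- as.numeric(res$resid)
    grouping[[tr]] <- res$grouping
  }
  attr(out, "grouping") <- grouping
  out
}

#' Fast-slow life-history axis from adjusted traits
#'
#' Principal component analysis of the four mass- and kinship-adjusted
#' traits (centered, scaled to unit variance). Axis signs are fixed so
#' that offspring and reproductive events load positively on PC1: high
#' PC1 = fast species (short-lived, early-maturing, high fecundity), low
#' PC1 = slow species.
#'
#' @param residuals output of [mass_adjust()].
#' @return object of class `life_history_pca`: list with `scores` (tibble:
#'   species, pc1..pc4), `loadings` (trait x axis matrix),
#'   `variance_explained` (per-axis fraction).
#' @export
fast_slow_pca <- function(residuals) {
  trait_cols <- intersect(c("longevity", "maturity", "reproductive_events",
                            "offspring"), names(residuals))
  if (length(trait_cols) < 2L) abort("need at least two residual traits")
  if (nrow(residuals) < 4L) abort("need at least 4 species")
  X <- as.matrix(residuals[trait_cols])
  sds <- apply(X, 2, sd)
  if (any(sds < .Machine$double.eps)) {
    abort(paste("constant residual trait column:",
                paste(trait_cols[sds < .Machine$double.eps],
                      collapse = ", ")))
  }
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  # orientation: fast (fecund) species get high PC1
  fec <- intersect(c("offspring", "reproductive_events"), trait_cols)
  if (sum(p$rotation[fec, 1]) < 0) {
    p$rotation[, 1] <- -p$rotation[, 1]
    p$x[, 1] <- -p$x[, 1]
  }
  for (j in seq(2, ncol(p$rotation))) { # deterministic sign elsewhere
    if (p$rotation[which.max(abs(p$rotation[, j])), j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  scores <- tibble::as_tibble(p$x)
  names(scores) <- paste0("pc", seq_len(ncol(scores)))
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(species = residuals$species),
                              scores),
    loadings = p$rotation,
    variance_explained = p$sdev^2 / sum(p$sdev^2)
  ), class = "life_history_pca")
}

#' @export
print.life_history_pca <- function(x, ...) {
  cat("<life_history_pca>", nrow(x$scores), "species\n")
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Life-history scores from raw trait records
#'
#' End-to-end trait pipeline: taxonomy harmonization (optional),
#' aggregation, phylogenetic eigenvectors, random-forest imputation, mass
#' and kinship adjustment, and the fast-slow PCA.
#'
#' @param records raw trait records (one or more rows per species).
#' @param tree phylogeny (`ape::phylo`) used for the eigenvectors;
#'   optional.
#' @param synonyms optional synonym table for [harmonize_taxonomy()].
#' @param seed imputation seed.
#' @return a `life_history_pca` object; the completed trait table is in
#'   the `traits` attribute.
#' @export
life_history_scores <- function(records, tree = NULL, synonyms = NULL,
                                seed = 42L) {
  if (!is.null(synonyms)) records <- harmonize_taxonomy(records, synonyms)
  agg <- aggregate_traits(records)
  ev <- if (!is.null(tree) &&
              length(tree$tip.label) >= 11L) {
    phylo_eigenvectors(tree, species = agg$species)
  } else NULL
  completed <- impute_traits(agg, eigenvectors = ev, seed = seed)
  res <- mass_adjust(completed)
  pca <- fast_slow_pca(res)
  attr(pca, "traits") <- completed
  pca
}
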