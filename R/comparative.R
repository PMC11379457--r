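# Comparative statistics: mixed-model species effects on a per-domain trait,
# and phylogenetic independent contrasts (PIC) correlation.

#' Species effects on a domain-level trait
#'
#' Fits (by REML) the linear mixed model \code{value ~ 0 + species +
#' (1 | domain)}: a fixed effect per species with a random intercept per
#' protein domain, so that compositional differences between species'
#' domain repertoires do not masquerade as species effects. Effects are
#' reported under a sum-to-zero identification (any constant shift cancels
#' in downstream contrasts). The significance of the random term is a
#' likelihood-ratio test against the fixed-effects-only model, with the
#' usual halved chi-squared(1) p-value for a variance on the boundary.
#'
#' @param table data.frame with columns \code{species}, \code{domain},
#'   \code{value} (as produced by \code{\link{simulate_trait_table}}).
#' @param transform Optional transform applied to \code{value} before
#'   fitting (default identity).
#' @return Object of class \code{"species_effects"}: data.frame
#'   (\code{species}, \code{effect}, \code{se}) with attributes
#'   \code{domain_sd}, \code{residual_sd}, \code{p_random} and
#'   \code{method} (\code{"reml"} or \code{"centered_means"} when the
#'   mixed fit is singular or degenerate).
#' @export
species_effects <- function(table, transform = identity) {
  stopifnot(all(c("species", "domain", "value") %in% names(table)))
  table$species <- factor(table$species)
  table$domain <- factor(table$domain)
  table$value <- transform(table$value)
  if (nlevels(table$species) < 2L) stop("need at least 2 species")
  if (any(table(table$species) < 1L)) stop("every species needs observations")

  fallback <- function() {
    # domain-centered means: effect = mean over domains of
    # (value - that domain's across-species mean)
    dmean <- tapply(table$value, table$domain, mean)
    resid <- table$value - dmean[as.character(table$domain)]
    eff <- tapply(resid, table$species, mean)
    eff <- eff - mean(eff)
    se <- tapply(resid, table$species, stats::sd) /
      sqrt(tabulate(table$species))
    out <- data.frame(species = levels(table$species),
                      effect = as.numeric(eff), se = as.numeric(se))
    attr(out, "domain_sd") <- stats::sd(dmean)
    attr(out, "residual_sd") <- NA_real_
    attr(out, "p_random") <- NA_real_
    attr(out, "method") <- "centered_means"
    class(out) <- c("species_effects", "data.frame")
    out
  }

  if (nlevels(table$domain) < 2L) {
    # single domain: model reduces to species means, random sd is 0
    eff <- tapply(table$value, table$species, mean)
    eff0 <- eff - mean(eff)
    se <- tapply(table$value, table$species, stats::sd) /
      sqrt(tabulate(table$species))
    out <- data.frame(species = levels(table$species),
                      effect = as.numeric(eff0), se = as.numeric(se))
    attr(out, "domain_sd") <- 0
    attr(out, "residual_sd") <- stats::sd(unlist(
      tapply(table$value, table$species, function(v) v - mean(v))))
    attr(out, "p_random") <- NA_real_
    attr(out, "method") <- "species_means"
    class(out) <- c("species_effects", "data.frame")
    return(out)
  }

  fit <- tryCatch(
    lme4::lmer(value ~ 0 + species + (1 | domain), data = table, REML = TRUE),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-8)) return(fallback())

  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  domain_sd <- vc$sdcor[vc$grp == "domain"]
  residual_sd <- vc$sdcor[vc$grp == "Residual"]
  # LRT for the random term (ML fits), boundary-corrected p-value
  p_random <- tryCatch({
    fit_ml <- lme4::lmer(value ~ 0 + species + (1 | domain), data = table,
                         REML = FALSE)
    fit0 <- stats::lm(value ~ 0 + species, data = table)
    stat <- max(0, 2 * (as.numeric(stats::logLik(fit_ml)) -
                          as.numeric(stats::logLik(fit0))))
    0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }, error = function(e) NA_real_)

  out <- data.frame(species = sub("^species", "", names(fe)),
                    effect = as.numeric(fe - mean(fe)),
                    se = as.numeric(se))
  attr(out, "domain_sd") <- domain_sd
  attr(out, "residual_sd") <- residual_sd
  attr(out, "p_random") <- p_random
  attr(out, "method") <- "reml"
  class(out) <- c("species_effects", "data.frame")
  out
}

#' @export
print.species_effects <- function(x, ...) {
  cat(sprintf("Species effects (%s): %d species; among-domain sd %.4f, residual sd %s, p(random) %s\n",
              attr(x, "method"), nrow(x), attr(x, "domain_sd"),
              format(attr(x, "residual_sd"), digits = 4),
              format(attr(x, "p_random"), digits = 3)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

.match_tip_values <- function(tree, x, what = "x") {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label)) {
      stop(what, " must be named by species or match the number of tips")
    }
    names(x) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(x))
  extra <- setdiff(names(x), tree$tip.label)
  if (length(missing) || length(extra)) {
    stop("tip/label mismatch for ", what,
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; not in tree: ",
                                   paste(extra, collapse = ", ")))
  }
  x[tree$tip.label]
}

#' Phylogenetic independent contrasts correlation of two traits
#'
#' Standardized contrasts (Felsenstein's pruning: at each internal node the
#' tip-value difference divided by the square root of the summed branch
#' lengths, with ancestral values propagated as weighted averages and
#' branches extended by \eqn{v_1 v_2/(v_1+v_2)}) are computed with
#' \code{ape::pic}; correlation, slope and \eqn{R^2} are then taken
#' through the origin, consistent with contrasts having expectation zero.
#'
#' @param tree \code{phylo} with branch lengths, or a path to a Newick
#'   file. Polytomies are resolved arbitrarily into zero-length branches
#'   and offset by \code{polytomy_eps}.
#' @param x,y Named numeric vectors of species values (names must match
#'   tip labels).
#' @param negate_x,negate_y Flip the sign of a trait (ENC is conventionally
#'   plotted negated so that larger means more adapted).
#' @param polytomy_eps Branch length given to zero-length branches created
#'   by polytomy resolution (default 1e-8 of tree height).
#' @return Object of class \code{"pic_cor"}: \code{r}, \code{r_squared},
#'   \code{slope} (y on x through the origin), \code{n_contrasts}, and the
#'   contrast matrix.
#' @export
pic_correlation <- function(tree, x, y, negate_x = FALSE, negate_y = FALSE,
                            polytomy_eps = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree)
    if (is.null(polytomy_eps)) {
      polytomy_eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
    }
    tree$edge.length[tree$edge.length == 0] <- polytomy_eps
  }
  term <- tree$edge[, 2] <= length(tree$tip.label)
  if (any(tree$edge.length[term] <= 0)) {
    stop("zero-length terminal branch(es); add a small jitter ",
         "(e.g. tree$edge.length + eps) before computing contrasts")
  }
  x <- .match_tip_values(tree, x, "x")
  y <- .match_tip_values(tree, y, "y")
  if (negate_x) x <- -x
  if (negate_y) y <- -y
  cx <- ape::pic(x, tree)
  cy <- ape::pic(y, tree)
  sxx <- sum(cx^2); syy <- sum(cy^2); sxy <- sum(cx * cy)
  r <- sxy / sqrt(sxx * syy)
  structure(list(r = r, r_squared = r^2, slope = sxy / sxx,
                 n_contrasts = length(cx),
                 contrasts = cbind(x = cx, y = cy)),
            class = "pic_cor")
}

#' @export
print.pic_cor <- function(x, ...) {
  cat(sprintf("PIC correlation: r = %.4f (R^2 = %.4f, slope = %.4f, %d contrasts)\n",
              x$r, x$r_squared, x$slope, x$n_contrasts))
  invisible(x)
}

#' Correlate species effects with a codon adaptation metric, tree-corrected
#'
#' @param effects A \code{\link{species_effects}} result (or named vector
#'   of species effects).
#' @param metric Named numeric vector of per-species metric values (CAIS,
#'   ENC, ...).
#' @param tree \code{phylo} or Newick path.
#' @param negate_metric Negate the metric (use for ENC, so higher means
#'   more effective selection).
#' @return A \code{\link{pic_correlation}} result over the shared species.
#' @export
correlate_adaptation <- function(effects, metric, tree,
                                 negate_metric = FALSE) {
  if (inherits(effects, "species_effects")) {
    effects <- stats::setNames(effects$effect, effects$species)
  }
  if (is.null(names(effects)) || is.null(names(metric))) {
    stop("effects and metric must be named by species")
  }
  if (is.character(tree)) tree <- ape::read.tree(tree)
  shared <- Reduce(intersect, list(names(effects), names(metric),
                                   tree$tip.label))
  if (length(shared) < 3L) stop("need at least 3 shared species")
  drop <- setdiff(tree$tip.label, shared)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  pic_correlation(tree, x = metric[shared], y = effects[shared],
                  negate_x = negate_metric)
}
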