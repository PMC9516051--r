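# Exact tests and segregation expectations used throughout the analyses,
# implemented from first principles so every p-value can be checked against
# brute-force enumeration.

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop("expected a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Conditions on both margins; the two-sided p-value is the sum of the
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (the
#' standard small-probabilities convention).
#'
#' @param table 2x2 matrix (rows = group, columns = outcome) of
#'   non-negative integer counts.
#' @return The two-tailed p-value. A degenerate table (a zero row or
#'   column margin) returns 1 with a warning.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as_2x2(table)
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    warning("degenerate margin: p = 1 by convention")
    return(1)
  }
  support <- max(0, r1 - (n - c1)):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Statistic `N * (max(0, |ad - bc| - N/2))^2 / (r1 r2 c1 c2)` on one
#' degree of freedom, with the continuity correction clamped at zero; the
#' two-tailed p-value comes from the chi-square survival function.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return `list(statistic, p_value)`.
#' @export
chi2_yates <- function(table) {
  m <- as_2x2(table)
  r <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(r == 0) || any(cs == 0))
    stop("zero margin: chi-square undefined", call. = FALSE)
  d <- abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  stat <- n * max(0, d - n / 2)^2 / (r[1] * r[2] * cs[1] * cs[2])
  list(statistic = unname(stat),
       p_value = unname(pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Two-sided exact binomial test
#'
#' Sums the probabilities of all outcomes whose probability under the null
#' does not exceed that of the observed count (small-probabilities
#' convention).
#'
#' @param k Observed successes (0..n).
#' @param n Trials.
#' @param p0 Null success probability, in (0, 1).
#' @return The two-sided p-value.
#' @export
binomial_two_sided <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  probs <- dbinom(0:n, n, p0)
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
}

#' Two-sample Student t test
#'
#' Classic two-tailed two-sample t test with pooled variance (equal
#' variances assumed); set `var_equal = FALSE` for the Welch form.
#'
#' @param x,y Numeric vectors, at least 2 values each.
#' @param var_equal Pool the variances (default) or use Welch df.
#' @return `list(statistic, df, p_value)`. With zero variance in both
#'   groups: equal means give p = 1, unequal means give p = 0 (flagged
#'   degenerate with a warning).
#' @export
t_two_sample <- function(x, y, var_equal = TRUE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group",
                             call. = FALSE)
  v1 <- var(x); v2 <- var(y)
  dm <- mean(x) - mean(y)
  if (v1 == 0 && v2 == 0) {
    warning("zero variance in both groups: degenerate test")
    p <- if (dm == 0) 1 else 0
    return(list(statistic = if (dm == 0) 0 else sign(dm) * Inf,
                df = NA_real_, p_value = p))
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- dm / se
  list(statistic = stat, df = df,
       p_value = 2 * pt(abs(stat), df, lower.tail = FALSE))
}

#' Haldane map function
#'
#' Converts a map distance in centimorgans to a recombination fraction,
#' `r = (1 - exp(-2 d)) / 2` with `d` in Morgans.
#'
#' @param d_cM Map distance in centimorgans.
#' @return Recombination fraction in \[0, 0.5).
#' @export
haldane <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Gamete class probabilities for a one- or two-locus cross model
#'
#' Enumerates the gamete classes produced by a parent of the given
#' genotypes. Alleles are written `+` (wild-type) and `-` (mutant); a class
#' label concatenates one allele per locus, e.g. `"--"` is the
#' double-mutant gamete. For two heterozygous loci the recombination
#' fraction comes from `map_cM` via [haldane()] (`NULL` = unlinked,
#' r = 1/2; 0 cM collapses the classes to parental types). `phase`
#' gives the parental arrangement of a double heterozygote: `"coupling"`
#' puts both mutant alleles on one homolog. An optional `selection` keeps
#' only the named classes and renormalizes, modelling phenotypic selection
#' of progeny or gametophytes.
#'
#' Examples of expectations this reproduces: a double-mutant
#' megagametophyte from an unlinked double heterozygote has probability
#' 1/4 (hence 1 defective : 3 normal kernels if every double-mutant
#' megagametophyte makes a defective kernel), and gametes lacking both of
#' two unlinked heterozygous markers (non-fluorescent kernels in a
#' two-marker screen crossed to wild-type) also 1/4.
#'
#' @param genotypes Character vector (one per locus, at most two loci) in
#'   `{"het", "hom_wt", "hom_mut"}`.
#' @param map_cM Map distance between two loci in cM; `NULL` = unlinked.
#' @param phase `"coupling"` or `"repulsion"` (two heterozygous loci only).
#' @param selection Optional character vector of class labels to condition
#'   on.
#' @return Named numeric vector of class probabilities summing to 1.
#' @export
segregation_expectation <- function(genotypes, map_cM = NULL,
                                    phase = c("coupling", "repulsion"),
                                    selection = NULL) {
  phase <- match.arg(phase)
  ok <- genotypes %in% c("het", "hom_wt", "hom_mut")
  if (!all(ok)) stop("genotypes must be het, hom_wt or hom_mut",
                     call. = FALSE)
  n_loci <- length(genotypes)
  if (n_loci < 1 || n_loci > 2)
    stop("one or two loci supported", call. = FALSE)
  if (!is.null(map_cM) && (n_loci < 2 || sum(genotypes == "het") < 2))
    stop("map_cM requires two heterozygous loci", call. = FALSE)
  allele <- list(het = c("+", "-"), hom_wt = "+", hom_mut = "-")
  if (n_loci == 1) {
    al <- allele[[genotypes]]
    probs <- stats::setNames(rep(1 / length(al), length(al)), al)
  } else {
    a1 <- allele[[genotypes[1]]]
    a2 <- allele[[genotypes[2]]]
    grid <- expand.grid(l1 = a1, l2 = a2, stringsAsFactors = FALSE)
    lab <- paste0(grid$l1, grid$l2)
    if (all(genotypes == "het")) {
      r <- if (is.null(map_cM)) 0.5 else haldane(map_cM)
      parental <- if (phase == "coupling") c("++", "--") else c("+-", "-+")
      p <- ifelse(lab %in% parental, (1 - r) / 2, r / 2)
    } else {
      p <- rep(1 / nrow(grid), nrow(grid))
    }
    probs <- stats::setNames(p, lab)
  }
  probs <- probs[probs > 0]
  if (!is.null(selection)) {
    bad <- setdiff(selection, names(probs))
    if (length(bad))
      stop("selection names unknown class(es): ", paste(bad, collapse = ", "),
           call. = FALSE)
    probs <- probs[names(probs) %in% selection]
    probs <- probs / sum(probs)
  }
  probs
}
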