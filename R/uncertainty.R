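## GUM-compliant combined uncertainty via the Kragten one-at-a-time
## numerical method, with a seeded Monte Carlo cross-check and the
## peptide-level budget over the full quantification chain.

#' Declare an uncertain input quantity
#'
#' @param name input name (unique within a budget).
#' @param value best estimate.
#' @param u standard uncertainty (k = 1).
#' @param dist distribution tag: `"normal"`, `"rectangular"` or `"derived"`
#'   (propagated quantities; sampled as normal by the Monte Carlo check).
#' @return one-row data.frame; `rbind` rows to build an input set.
#' @export
uncertain_input <- function(name, value, u,
                            dist = c("normal", "rectangular", "derived")) {
  dist <- match.arg(dist)
  stopifnot(is.character(name), length(name) == 1L, u >= 0)
  data.frame(name = name, value = value, u = u, dist = dist,
             stringsAsFactors = FALSE)
}

.as_input_frame <- function(inputs) {
  if (is.data.frame(inputs)) {
    stopifnot(all(c("name", "value", "u") %in% names(inputs)))
    if (is.null(inputs$dist)) inputs$dist <- "normal"
  } else stop("inputs must be a data.frame of uncertain_input rows")
  if (anyDuplicated(inputs$name))
    stop("duplicated input names: ",
         paste(unique(inputs$name[duplicated(inputs$name)]), collapse = ", "))
  inputs
}

#' Kragten numerical uncertainty propagation
#'
#' Classic spreadsheet-style GUM evaluation: the measurement function is
#' re-evaluated with each input shifted by +u one at a time;
#' `c_i = f(x_i + u_i) - f(x)` approximates the sensitivity-weighted
#' contribution, the combined standard uncertainty is the quadrature sum of
#' the `c_i`, and each input's *index* is its percentage share of the
#' combined variance. Exact for affine measurement functions; for smooth
#' non-linear functions it carries benign second-order terms. A symmetric
#' variant `(f(x+u) - f(x-u)) / 2` is available.
#'
#' @param f measurement function; receives a named list of input values and
#'   must return a single finite numeric.
#' @param inputs data.frame of [uncertain_input()] rows.
#' @param k coverage factor for the expanded uncertainty (default 2).
#' @param symmetric use the symmetric two-sided shift (default FALSE: the
#'   classic +u shift).
#' @return Object of class `uncertainty_budget`: `value`, `u` (combined,
#'   k = 1), `U`, `k`, `u_rel`, per-input `contributions` and `indexes`
#'   (percent of combined variance), and the `inputs` used.
#' @examples
#' ins <- rbind(uncertain_input("x", 10, 3), uncertain_input("y", 5, 4))
#' kragten(function(v) v$x + v$y, ins)$u # 5
#' @export
kragten <- function(f, inputs, k = 2, symmetric = FALSE) {
  inputs <- .as_input_frame(inputs)
  x0 <- as.list(stats::setNames(inputs$value, inputs$name))
  y0 <- f(x0)
  if (!is.numeric(y0) || length(y0) != 1L || !is.finite(y0))
    stop("measurement function must return a single finite value at the ",
         "input estimates")
  contrib <- vapply(seq_len(nrow(inputs)), function(i) {
    xp <- x0; xp[[inputs$name[i]]] <- inputs$value[i] + inputs$u[i]
    yp <- f(xp)
    if (!is.finite(yp))
      stop("measurement function not finite when shifting input '",
           inputs$name[i], "'")
    if (!symmetric) return(yp - y0)
    xm <- x0; xm[[inputs$name[i]]] <- inputs$value[i] - inputs$u[i]
    ym <- f(xm)
    if (!is.finite(ym))
      stop("measurement function not finite when shifting input '",
           inputs$name[i], "'")
    (yp - ym) / 2
  }, numeric(1))
  names(contrib) <- inputs$name
  var_c <- sum(contrib^2)
  idx <- if (var_c > 0) 100 * contrib^2 / var_c else contrib * 0
  structure(list(value = y0, u = sqrt(var_c), U = k * sqrt(var_c), k = k,
                 u_rel = if (y0 != 0) sqrt(var_c) / abs(y0) else NA_real_,
                 contributions = contrib, indexes = idx, inputs = inputs),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("value = %.6g, u = %.3g (u_rel = %s), U(k=%g) = %.3g\n",
              x$value, x$u,
              if (is.na(x$u_rel)) "n/a" else sprintf("%.2f%%", 100 * x$u_rel),
              x$k, x$U))
  ord <- order(x$indexes, decreasing = TRUE)
  for (i in ord)
    cat(sprintf("  %-18s index %5.1f%%\n", names(x$indexes)[i],
                x$indexes[i]))
  invisible(x)
}

#' Monte Carlo propagation (oracle for the Kragten budget)
#'
#' Samples every input from its tagged distribution (`normal`: mean = value,
#' sd = u; `rectangular`: uniform over value +/- u*sqrt(3); `derived` is
#' sampled as normal) and returns the sample standard deviation of the
#' output and a percentile interval. Seeded and reproducible. The
#' measurement function is called once with vectors of draws, so it must be
#' vectorised (all arithmetic chains are); a non-vectorisable function is
#' evaluated draw by draw.
#'
#' @inheritParams kragten
#' @param n_draws number of draws (>= 1000).
#' @param seed RNG seed.
#' @param probs percentile interval probabilities.
#' @return list with `u` (sample sd), `mean`, `interval`, `n_draws`, `seed`.
#' @export
monte_carlo_u <- function(f, inputs, n_draws = 1e5, seed = 1,
                          probs = c(0.025, 0.975)) {
  inputs <- .as_input_frame(inputs)
  if (n_draws < 1000) stop("n_draws must be at least 1000")
  bad <- setdiff(inputs$dist, c("normal", "rectangular", "derived"))
  if (length(bad))
    stop("unknown distribution tag(s): ", paste(bad, collapse = ", "))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- lapply(seq_len(nrow(inputs)), function(i) {
    v <- inputs$value[i]; u <- inputs$u[i]
    if (inputs$dist[i] == "rectangular" && u > 0)
      stats::runif(n_draws, v - u * sqrt(3), v + u * sqrt(3))
    else if (u > 0) stats::rnorm(n_draws, v, u)
    else rep(v, n_draws)
  })
  names(draws) <- inputs$name
  y <- tryCatch(f(draws), error = function(e) NULL)
  if (is.null(y) || length(y) != n_draws)
    y <- vapply(seq_len(n_draws), function(j)
      f(lapply(draws, `[[`, j)), numeric(1))
  list(u = stats::sd(y), mean = mean(y),
       interval = stats::quantile(y, probs, names = FALSE),
       n_draws = n_draws, seed = seed)
}

# the composed mass-fraction -> TCMP measurement function; v is the named
# input list of a Kragten/MC evaluation
.tcmp_chain <- function(v) {
  w <- v$b_pep * v$m_Exsolv / (v$m_X * v$m_Extr) * v$M_j *
    v$f_ext * v$f_dig * v$f_purity * 1e6
  if (!is.null(v$digestion_scatter)) w <- w * v$digestion_scatter
  if (is.null(v$CF)) w else w / v$CF
}

.budget_inputs <- function(b, grav, molar_mass, cf, factors, u_mass_g,
                           scatter_rel = NULL) {
  nm <- c("b_pep", "f_purity", "f_ext", "f_dig", "m_X", "m_Exsolv",
          "m_Extr", "M_j")
  val <- c(b$value, 1, 1, 1, grav$m_x, grav$m_exsolv, grav$m_extr,
           molar_mass$value)
  u <- c(b$u, factors$f_purity$u, factors$f_ext$u, factors$f_dig$u,
         u_mass_g, u_mass_g, u_mass_g, molar_mass$u)
  dist <- c("normal", "rectangular", "normal", "normal", "normal", "normal",
            "normal", "rectangular")
  if (!is.null(cf)) {
    nm <- c(nm, "CF"); val <- c(val, cf$value); u <- c(u, cf$u)
    dist <- c(dist, "derived")
  }
  if (!is.null(scatter_rel)) {
    nm <- c(nm, "digestion_scatter"); val <- c(val, 1)
    u <- c(u, scatter_rel); dist <- c(dist, "normal")
  }
  data.frame(name = nm, value = val, u = u, dist = dist,
             stringsAsFactors = FALSE)
}

.group_indexes <- function(budget) {
  idx <- budget$indexes
  g <- c(f_purity = unname(idx["f_purity"]),
         b_pep = unname(idx["b_pep"]),
         M_j = unname(idx["M_j"]),
         f_ext = unname(idx["f_ext"]),
         f_dig = unname(idx["f_dig"]),
         CF = if ("CF" %in% names(idx)) unname(idx["CF"]) else 0,
         masses = sum(idx[c("m_X", "m_Exsolv", "m_Extr")]))
  if ("digestion_scatter" %in% names(idx))
    g["digestion_scatter"] <- unname(idx["digestion_scatter"])
  g
}

#' Uncertainty budget for one signature peptide
#'
#' Applies [kragten()] to the composed measurement chain
#' molality -> protein mass fraction -> TCMP for one peptide: inputs are the
#' molality `b_pep`, the purity / extraction / digestion unity factors, the
#' three weighed masses, the protein molar mass `M_j` and the conversion
#' factor `CF`. Emits the familiar budget-report shape: TCMP value, expanded
#' uncertainty and percent index per input group.
#'
#' @param b peptide molality as a [measurement()] (mol/g).
#' @param grav a [gravimetric_record()].
#' @param molar_mass protein molar mass [measurement()] (g/mol).
#' @param cf protein conversion factor [measurement()].
#' @param factors a [unity_factors()] list.
#' @param u_mass_g standard uncertainty of one weighing, g.
#' @param k coverage factor.
#' @return An `uncertainty_budget` with an extra `index_groups` element
#'   (percent contribution of f_purity, b_pep, M_j, f_ext, f_dig, CF and the
#'   pooled weighed masses).
#' @export
budget_for_peptide <- function(b, grav = gravimetric_record(), molar_mass,
                               cf, factors = unity_factors(),
                               u_mass_g = 5e-4, k = 2) {
  stopifnot(is.measurement(b), is.measurement(molar_mass), is.measurement(cf))
  ins <- .budget_inputs(b, grav, molar_mass, cf, factors, u_mass_g)
  bud <- kragten(.tcmp_chain, ins, k = k)
  bud$index_groups <- .group_indexes(bud)
  bud
}

#' Uncertainty budget for one marker protein
#'
#' Same chain as [budget_for_peptide()] evaluated at the mean molality of
#' the protein's peptides, with the between-peptide standard error of the
#' mean entering as an additional independent unity input
#' (`digestion_scatter`), as prescribed for incomplete-proteolysis scatter.
#' Also evaluates the chain without the CF division, giving the mass
#' fraction `w_j` and its uncertainty (needed by the A3/A4 sums).
#'
#' @inheritParams budget_for_peptide
#' @param scatter_rel relative between-peptide SEM (0 for single-peptide
#'   proteins).
#' @return An `uncertainty_budget` (TCMP scale) with `index_groups` plus
#'   `value_w` and `value_w_u`: the protein mass fraction (mg/kg) and its
#'   combined standard uncertainty before the CF conversion.
#' @export
budget_for_protein <- function(b, grav = gravimetric_record(), molar_mass,
                               cf, factors = unity_factors(),
                               scatter_rel = 0, u_mass_g = 5e-4, k = 2) {
  stopifnot(is.measurement(b), is.measurement(molar_mass), is.measurement(cf))
  ins <- .budget_inputs(b, grav, molar_mass, cf, factors, u_mass_g,
                        scatter_rel = scatter_rel)
  bud <- kragten(.tcmp_chain, ins, k = k)
  bud$index_groups <- .group_indexes(bud)
  ins_w <- ins[ins$name != "CF", ]
  bud_w <- kragten(.tcmp_chain, ins_w, k = k)
  bud$value_w <- bud_w$value
  bud$value_w_u <- bud_w$u
  bud
}

#' Budget report table
#'
#' Collects per-peptide budgets into the standard report layout: one row per
#' peptide with the TCMP value, expanded uncertainty, relative standard
#' uncertainty and the percent indexes of the main input quantities.
#'
#' @param budgets named list of budgets from [budget_for_peptide()].
#' @return data.frame with columns `peptide, w_tcmp, U_k2, u_rel_pct,
#'   idx_f_purity, idx_b_pep, idx_M, idx_f_ext, idx_f_dig, idx_CF,
#'   idx_masses`.
#' @export
budget_table <- function(budgets) {
  out <- do.call(rbind, lapply(names(budgets), function(pep) {
    b <- budgets[[pep]]
    g <- b$index_groups
    data.frame(peptide = pep, w_tcmp = b$value, U_k2 = b$k * b$u,
               u_rel_pct = 100 * b$u_rel,
               idx_f_purity = g[["f_purity"]], idx_b_pep = g[["b_pep"]],
               idx_M = g[["M_j"]], idx_f_ext = g[["f_ext"]],
               idx_f_dig = g[["f_dig"]], idx_CF = g[["CF"]],
               idx_masses = g[["masses"]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
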