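# Planted-truth generation: oxygen-response classes, engagement weights,
# ribosome loads, turnover, and overlapping RBP dependency portfolios.

#' Largest-remainder apportionment of class counts
#'
#' Deterministically rounds `n * proportions` to integers summing to `n`:
#' floor each share, then hand the remaining units to the classes with the
#' largest fractional remainders (ties broken by position).
#'
#' @param n Total count (non-negative integer).
#' @param proportions Non-negative numeric vector summing to 1.
#' @return Integer vector of counts, same names as `proportions`.
#' @export
largest_remainder <- function(n, proportions) {
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  exact <- n * proportions
  counts <- floor(exact)
  left <- n - sum(counts)
  if (left > 0) {
    rem <- exact - counts
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' RBP portfolio configuration for the generator
#'
#' Describes the dependency portfolios planted into a synthetic truth table:
#' how many targets each RBP has, which pairs of portfolios share targets (and
#' how many), and the multiplicative effect sizes that silencing each RBP has
#' on target protein output, translation efficiency, and steady-state RNA.
#'
#' Shared targets are planted pairwise: an entity belongs to at most two
#' portfolios, so requested pairwise intersection sizes are met exactly.
#'
#' @param portfolios Named integer vector: portfolio size per RBP.
#' @param overlaps Data frame with columns `a`, `b`, `size`: requested exact
#'   pairwise intersection sizes. `NULL` means no shared targets.
#' @param output_effect Multiplicative effect of silencing an RBP on the
#'   protein output of its targets (scalar or named per RBP; 1 = no effect;
#'   values below 1 mean the RBP promotes output).
#' @param te_effect Planted knockdown/control translation-efficiency ratio for
#'   targets (scalar or named per RBP).
#' @param rna_effect Planted knockdown/control steady-state RNA ratio for
#'   targets (scalar or named per RBP).
#' @param class3_weight Sampling weight of hypoxia-induced (class III)
#'   entities when drawing portfolio members; > 1 enriches portfolios for the
#'   hypoxia-inducible population, as observed for hypoxia-adaptive RBPs.
#' @return A list of class `rbp_config`.
#' @export
rbp_config <- function(portfolios = c(HuR = 80, PCBP1 = 80, PCBP2 = 80,
                                      hnRNPA2B1 = 80, PTBP1 = 80),
                       overlaps = NULL,
                       output_effect = 0.7,
                       te_effect = 0.25,
                       rna_effect = 1,
                       class3_weight = 3) {
  if (length(portfolios) && is.null(names(portfolios))) {
    stop("`portfolios` must be a named vector (names = RBPs)")
  }
  if (any(portfolios < 0)) stop("portfolio sizes must be non-negative")
  rbps <- names(portfolios)
  if (!is.null(overlaps)) {
    overlaps <- as.data.frame(overlaps)
    if (!all(c("a", "b", "size") %in% names(overlaps))) {
      stop("`overlaps` needs columns a, b, size")
    }
    bad <- setdiff(unique(c(overlaps$a, overlaps$b)), rbps)
    if (length(bad)) stop("overlap names not in portfolios: ",
                          paste(bad, collapse = ", "))
  }
  expand <- function(x) {
    if (length(x) == 1 && is.null(names(x))) {
      return(stats::setNames(rep(as.numeric(x), length(rbps)), rbps))
    }
    if (!all(rbps %in% names(x))) stop("per-RBP effects must name every RBP")
    stats::setNames(as.numeric(x[rbps]), rbps)
  }
  structure(
    list(portfolios = stats::setNames(as.integer(portfolios), rbps),
         overlaps = overlaps,
         output_effect = expand(output_effect),
         te_effect = expand(te_effect),
         rna_effect = expand(rna_effect),
         class3_weight = as.numeric(class3_weight)),
    class = "rbp_config"
  )
}

#' Default five-RBP portfolio configuration
#'
#' Five portfolios of 80 targets each with 10 shared targets between
#' consecutive pairs, enriched threefold for class III entities. Silencing
#' reduces target protein output to 0.7x and translation efficiency to 0.25x
#' of control, with no steady-state RNA effect (translation-dominant
#' regulation).
#'
#' @return An `rbp_config`.
#' @export
default_rbp_config <- function() {
  rbps <- c("HuR", "PCBP1", "PCBP2", "hnRNPA2B1", "PTBP1")
  rbp_config(
    portfolios = stats::setNames(rep(80L, 5), rbps),
    overlaps = data.frame(a = rbps[-5], b = rbps[-1], size = 10L)
  )
}

# Move polysome/free mass ratio of weight triple (f, m, p) by factor `fold`,
# holding the monosome weight and the f+p total fixed.
shift_engagement <- function(w, fold) {
  f <- w[1]; m <- w[2]; p <- w[3]
  if (p == 0 || f == 0 || fold == 1) return(w)
  fp <- f + p
  f2 <- f * fp / (f + fold * p)
  p2 <- fold * p * fp / (f + fold * p)
  c(f2, m, p2)
}

#' Generate a planted-truth table
#'
#' Draws a synthetic population of entities (genes/proteins) with a known
#' oxygen-response class, planted hypoxia/normoxia output ratio, per-condition
#' engagement weights over the free/monosome/polysome compartments,
#' per-condition ribosome loads, protein turnover half-lives, gene lengths,
#' and per-RBP silencing effects. All downstream simulators consume this
#' table, so every estimator in the package can be checked against a known
#' answer.
#'
#' Class counts follow deterministic largest-remainder rounding of
#' `n_entities * class_proportions`. Planted output ratios respect the 15%
#' classification boundaries: class III entities have hypoxia/normoxia output
#' ratio >= 1.15, class I <= 0.85, class II strictly inside (0.85, 1.15).
#' Hypoxia shifts the polysome/free engagement ratio by a class-dependent
#' fold, and the hypoxic ribosome load is solved so the planted
#' translation-efficiency shift matches the planted output ratio.
#'
#' @param n_entities Number of entities (positive integer).
#' @param class_proportions Length-3 non-negative vector summing to 1, in
#'   class order (I, II, III). Default `c(0.2, 0.5, 0.3)`: roughly 30% of the
#'   population hypoxia-induced.
#' @param rbp_cfg An [rbp_config()]; `NULL` for no portfolios.
#' @param activation Optional list `list(n =, fold = 4, ids = NULL)` planting
#'   `n` entities whose hypoxic polysome/free engagement is `fold` times the
#'   class-default shift (MATRIX ranking spike-ins).
#' @param engagement_fold Named length-3 vector: hypoxia/normoxia
#'   polysome-to-free fold per class.
#' @param kmax Maximum ribosome count resolved by the intended gradient
#'   scheme (tail of the load distribution is lumped there).
#' @param seed Integer seed; identical seed and configuration reproduce the
#'   table exactly.
#' @return A data frame of class `truth_table`, one row per entity, with
#'   attributes `rbps`, `portfolios` (named list of planted target ids),
#'   `activated` (spike-in ids) and `params`.
#' @export
generate_truth <- function(n_entities,
                           class_proportions = c(I = 0.2, II = 0.5, III = 0.3),
                           rbp_cfg = default_rbp_config(),
                           activation = NULL,
                           engagement_fold = c(I = 0.8, II = 1, III = 1.25),
                           kmax = 8L,
                           seed = 1L) {
  if (n_entities < 1) stop("`n_entities` must be positive")
  if (length(class_proportions) != 3) {
    stop("`class_proportions` must have length 3 (classes I, II, III)")
  }
  class_proportions <- stats::setNames(as.numeric(class_proportions),
                                       c("I", "II", "III"))
  counts <- largest_remainder(n_entities, class_proportions)
  if (!is.null(rbp_cfg)) {
    stopifnot(inherits(rbp_cfg, "rbp_config"))
    if (any(rbp_cfg$portfolios > n_entities)) {
      stop("portfolio sizes must not exceed `n_entities`")
    }
    validate_overlaps(rbp_cfg, n_entities)
  }

  with_seed(seed, {
    entity_id <- sprintf("ENT%05d", seq_len(n_entities))
    class_label <- sample(rep(c("I", "II", "III"), counts))

    output_ratio <- numeric(n_entities)
    nI <- sum(class_label == "I"); nII <- sum(class_label == "II")
    nIII <- sum(class_label == "III")
    output_ratio[class_label == "I"] <- stats::runif(nI, 0.45, 0.85)
    output_ratio[class_label == "II"] <- stats::runif(nII, 0.86, 1.14)
    output_ratio[class_label == "III"] <- stats::runif(nIII, 1.15, 2.20)

    base_abundance <- stats::rlnorm(n_entities, log(50), 1)
    turnover_halflife <- stats::rlnorm(n_entities, log(30), 0.5)
    gene_length_kb <- stats::rlnorm(n_entities, log(2.5), 0.4)

    # normoxic engagement weights ~ Dirichlet(2, 2, 3)
    g <- cbind(stats::rgamma(n_entities, 2), stats::rgamma(n_entities, 2),
               stats::rgamma(n_entities, 3))
    w_n <- g / rowSums(g)

    fold <- unname(engagement_fold[class_label])
    activated <- character(0)
    if (!is.null(activation)) {
      if (is.null(activation$fold)) activation$fold <- 4
      ids <- activation$ids
      if (is.null(ids)) ids <- sample(entity_id, activation$n)
      activated <- ids
      fold[match(ids, entity_id)] <- activation$fold
    }
    w_h <- t(vapply(seq_len(n_entities),
                    function(i) shift_engagement(w_n[i, ], fold[i]),
                    numeric(3)))

    lambda_n <- stats::runif(n_entities, 0.5, 5)
    lambda_h <- vapply(seq_len(n_entities), function(i) {
      load_for_te_ratio(lambda_n[i], output_ratio[i], kmax)
    }, numeric(1))

    truth <- data.frame(
      entity_id = entity_id,
      class_label = class_label,
      output_ratio = output_ratio,
      base_abundance = base_abundance,
      turnover_halflife = turnover_halflife,
      gene_length_kb = gene_length_kb,
      w_free_normoxia = w_n[, 1], w_mono_normoxia = w_n[, 2],
      w_poly_normoxia = w_n[, 3],
      w_free_hypoxia = w_h[, 1], w_mono_hypoxia = w_h[, 2],
      w_poly_hypoxia = w_h[, 3],
      lambda_normoxia = lambda_n,
      lambda_hypoxia = lambda_h,
      stringsAsFactors = FALSE
    )

    portfolios <- list()
    if (!is.null(rbp_cfg) && length(rbp_cfg$portfolios)) {
      portfolios <- draw_portfolios(rbp_cfg, entity_id, class_label)
      for (r in names(portfolios)) {
        is_target <- entity_id %in% portfolios[[r]]
        truth[[paste0("effect_", r)]] <-
          ifelse(is_target, rbp_cfg$output_effect[r], 1)
        truth[[paste0("te_effect_", r)]] <-
          ifelse(is_target, rbp_cfg$te_effect[r], 1)
        truth[[paste0("rna_effect_", r)]] <-
          ifelse(is_target, rbp_cfg$rna_effect[r], 1)
      }
    }

    structure(truth,
              class = c("truth_table", "data.frame"),
              rbps = names(portfolios),
              portfolios = portfolios,
              activated = activated,
              params = list(n_entities = n_entities,
                            class_proportions = class_proportions,
                            engagement_fold = engagement_fold,
                            kmax = kmax, seed = seed))
  })
}

# Feasibility checks for requested pairwise portfolio intersections.
validate_overlaps <- function(cfg, n_entities) {
  ov <- cfg$overlaps
  sizes <- cfg$portfolios
  if (is.null(ov) || !nrow(ov)) {
    if (sum(sizes) > 0 && sum(sizes) > n_entities * length(sizes)) {
      stop("portfolio sizes exceed the entity pool")
    }
    return(invisible(TRUE))
  }
  for (i in seq_len(nrow(ov))) {
    a <- ov$a[i]; b <- ov$b[i]; s <- ov$size[i]
    if (s > min(sizes[a], sizes[b])) {
      stop("infeasible overlap for pair (", a, ", ", b, "): requested ",
           s, " exceeds a portfolio size")
    }
  }
  for (r in names(sizes)) {
    need <- sum(ov$size[ov$a == r | ov$b == r])
    if (need > sizes[r]) {
      stop("infeasible overlaps for portfolio ", r,
           ": pairwise shares sum to ", need, " > size ", sizes[r])
    }
  }
  distinct <- sum(sizes) - sum(ov$size)
  if (distinct > n_entities) {
    stop("portfolios need ", distinct, " distinct entities but only ",
         n_entities, " exist")
  }
  invisible(TRUE)
}

# Draw portfolios honoring exact pairwise intersections. Shared members are
# drawn first (one draw per requested pair, from the unused pool), then each
# portfolio is filled with exclusive members; an entity thus belongs to at
# most two portfolios and every requested |A intersect B| is exact.
draw_portfolios <- function(cfg, entity_id, class_label) {
  sizes <- cfg$portfolios
  w <- ifelse(class_label == "III", cfg$class3_weight, 1)
  pool <- seq_along(entity_id)
  members <- stats::setNames(vector("list", length(sizes)), names(sizes))
  for (r in names(sizes)) members[[r]] <- integer(0)
  ov <- cfg$overlaps
  if (!is.null(ov) && nrow(ov)) {
    for (i in seq_len(nrow(ov))) {
      s <- ov$size[i]
      if (s == 0) next
      pick <- sample(pool, s, prob = w[pool])
      pool <- setdiff(pool, pick)
      members[[ov$a[i]]] <- c(members[[ov$a[i]]], pick)
      members[[ov$b[i]]] <- c(members[[ov$b[i]]], pick)
    }
  }
  for (r in names(sizes)) {
    need <- sizes[r] - length(members[[r]])
    if (need > 0) {
      pick <- sample(pool, need, prob = w[pool])
      pool <- setdiff(pool, pick)
      members[[r]] <- c(members[[r]], pick)
    }
  }
  lapply(members, function(ix) entity_id[sort(ix)])
}

#' Planted dependency portfolios of a truth table
#' @param truth A `truth_table`.
#' @return Named list of entity-id character vectors, one per RBP.
#' @export
truth_portfolios <- function(truth) {
  stopifnot(inherits(truth, "truth_table"))
  attr(truth, "portfolios")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table> ", nrow(x), " entities; classes: ",
      paste(names(table(x$class_label)), table(x$class_label),
            sep = "=", collapse = " "),
      "; RBPs: ", paste(attr(x, "rbps"), collapse = ", "), "\n", sep = "")
  invisible(x)
}
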