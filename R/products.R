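# Stoichiometric oxide-to-elemental conversion factors:
# P = 2*30.974 / (2*30.974 + 5*15.999) of P2O5; K = 2*39.098 / (2*39.098 +
# 15.999) of K2O.  Fixed at the conventional 4-digit values.
P_FROM_P2O5 <- 0.4364
K_FROM_K2O <- 0.8301

#' The packaged fertilizer-product table
#'
#' The eight products and average farmgate prices used in the Odisha
#' trials: urea, muriate of potash (MOP, 0-0-60), diammonium phosphate
#' (DAP, 18-46-0), single superphosphate (SSP), zinc sulfate, two
#' compound NP fertilizers and one NPK fertilizer.  Grades are percent
#' N-P2O5-K2O by mass; prices are US$ per kg.
#'
#' @return data.frame with columns `name`, `grade_n`, `grade_p2o5`,
#'   `grade_k2o`, `price_usd_per_kg`
#' @export
default_products <- function() {
  data.frame(
    name = c("urea", "MOP", "DAP", "SSP", "zinc_sulfate",
             "NP_28_28_0", "NP_20_20_0", "NPK_10_26_26"),
    grade_n = c(46, 0, 18, 0, 0, 28, 20, 10),
    grade_p2o5 = c(0, 0, 46, 16, 0, 28, 20, 26),
    grade_k2o = c(0, 60, 0, 0, 0, 0, 0, 26),
    price_usd_per_kg = c(0.09, 0.26, 0.38, 0.14, 1.08, 0.38, 0.44, 0.36),
    stringsAsFactors = FALSE
  )
}

validate_products <- function(products) {
  need <- c("name", "grade_n", "grade_p2o5", "grade_k2o",
            "price_usd_per_kg")
  missing <- setdiff(need, names(products))
  if (length(missing))
    stop_input("product table missing column(s): ",
               paste(missing, collapse = ", "))
  g <- products[c("grade_n", "grade_p2o5", "grade_k2o")]
  if (any(g < 0) || any(g > 100) || any(rowSums(g) > 100))
    stop_input("grades must be in [0, 100] and sum to <= 100")
  if (any(products$price_usd_per_kg < 0)) stop_input("negative price")
  if (anyDuplicated(products$name)) stop_input("duplicate product names")
  invisible(products)
}

#' Convert a fertilizer grade to elemental mass fractions
#'
#' Grades are quoted as percent N-P2O5-K2O; elemental fractions use the
#' stoichiometric factors P = 0.4364 x P2O5 and K = 0.8301 x K2O.
#'
#' @param product one row of a product table (or any list with
#'   `grade_n`, `grade_p2o5`, `grade_k2o`)
#' @return named numeric vector `c(n, p, k)` of elemental mass fractions
#' @export
#' @examples
#' grade_to_elemental(list(grade_n = 18, grade_p2o5 = 46, grade_k2o = 0))
grade_to_elemental <- function(product) {
  c(n = product$grade_n / 100,
    p = P_FROM_P2O5 * product$grade_p2o5 / 100,
    k = K_FROM_K2O * product$grade_k2o / 100)
}

elemental_fractions <- function(products) {
  cbind(n = products$grade_n / 100,
        p = P_FROM_P2O5 * products$grade_p2o5 / 100,
        k = K_FROM_K2O * products$grade_k2o / 100)
}

#' Allocate a nutrient prescription to fertilizer products
#'
#' Deterministic priority allocation: (1) zinc sulfate at the flat
#' policy rate, basal, when `zinc` is on; (2) the basal P requirement is
#' met by the product with the highest elemental-P fraction; (3) each K
#' split is met by the product with the highest elemental-K fraction;
#' (4) N delivered incidentally by the P and K sources is credited
#' against the basal N split first, then mid-tillering, then panicle
#' initiation; (5) the residual N of each split is met by the
#' highest-N single-nutrient (N-only) product.  Demand that no product
#' can supply is reported as unmet, never dropped.  Ties are broken by
#' product-table order.
#'
#' @param prescription a [build_prescription()] result
#' @param products product table (see [default_products()])
#' @param cfg an [engine_config()]
#' @param zinc apply the flat zinc-sulfate policy?
#' @param zinc_product name of the zinc product in the table
#' @return object of class `product_allocation`: `applications`
#'   (stage, dat, product, amount_kg_ha), `delivered` and `unmet`
#'   elemental kg/ha, `zinc_sulfate` kg/ha
#' @export
allocate_products <- function(prescription, products,
                              cfg = engine_config(), zinc = TRUE,
                              zinc_product = "zinc_sulfate") {
  validate_products(products)
  if (nrow(products) == 0) stop_input("empty product list")
  frac <- elemental_fractions(products)
  basal_dat <- unname(prescription$schedule["basal"])
  apps <- list()
  add_app <- function(stage, dat, product, amount) {
    if (amount <= 1e-12) return(invisible(NULL))
    apps[[length(apps) + 1L]] <<- data.frame(
      stage = stage, dat = dat, product = product,
      amount_kg_ha = amount, stringsAsFactors = FALSE)
  }

  zinc_kg <- 0
  if (isTRUE(zinc) && cfg$zinc_sulfate_rate > 0) {
    if (!zinc_product %in% products$name)
      stop_input("zinc policy is on but product '", zinc_product,
                 "' is not in the table")
    zinc_kg <- cfg$zinc_sulfate_rate
    add_app("basal", basal_dat, zinc_product, zinc_kg)
  }

  # nutrient-bearing candidates; zinc sulfate carries no N/P/K here
  n_credit <- 0
  # (2) P, basal
  if (prescription$fp > 1e-12) {
    i <- which.max(frac[, "p"])
    if (frac[i, "p"] > 0) {
      amt <- prescription$fp / frac[i, "p"]
      add_app("basal", basal_dat, products$name[i], amt)
      n_credit <- n_credit + amt * frac[i, "n"]
    }
  }
  # (3) K, per split
  for (j in seq_len(nrow(prescription$k_splits))) {
    need <- prescription$k_splits$kg_per_ha[j]
    if (need <= 1e-12) next
    i <- which.max(frac[, "k"])
    if (frac[i, "k"] > 0) {
      amt <- need / frac[i, "k"]
      add_app(prescription$k_splits$stage[j], prescription$k_splits$dat[j],
              products$name[i], amt)
      n_credit <- n_credit + amt * frac[i, "n"]
    }
  }
  # (4) credit incidental N basal -> mid-tillering -> PI; (5) top up
  # each split with the highest-N single-nutrient product
  n_only <- which(products$grade_n > 0 & products$grade_p2o5 == 0 &
                    products$grade_k2o == 0)
  i_n <- if (length(n_only)) n_only[which.max(frac[n_only, "n"])] else NA
  for (j in seq_len(nrow(prescription$n_splits))) {
    need <- prescription$n_splits$kg_per_ha[j]
    used <- min(n_credit, need)
    n_credit <- n_credit - used
    resid <- need - used
    if (resid > 1e-12 && !is.na(i_n))
      add_app(prescription$n_splits$stage[j], prescription$n_splits$dat[j],
              products$name[i_n], resid / frac[i_n, "n"])
  }

  applications <- if (length(apps)) do.call(rbind, apps) else
    data.frame(stage = character(), dat = numeric(), product = character(),
               amount_kg_ha = numeric(), stringsAsFactors = FALSE)
  applications <- applications[order(applications$dat), , drop = FALSE]
  rownames(applications) <- NULL

  delivered <- delivered_nutrients(applications, products)
  required <- c(n = prescription$fn, p = prescription$fp,
                k = prescription$fk)
  unmet <- pmax(required - delivered, 0)
  unmet[unmet < 1e-9] <- 0
  if (any(unmet > 1e-6))
    warning("allocation leaves unmet demand (kg/ha): ",
            paste(sprintf("%s=%.2f", names(unmet)[unmet > 1e-6],
                          unmet[unmet > 1e-6]), collapse = ", "),
            call. = FALSE)
  structure(list(applications = applications, delivered = delivered,
                 unmet = unmet, zinc_sulfate = zinc_kg),
            class = "product_allocation")
}

#' Recompute delivered elemental nutrients from an application table
#'
#' @param applications data.frame with `product` and `amount_kg_ha`
#' @param products product table
#' @return named vector `c(n, p, k)` of elemental kg/ha
#' @export
delivered_nutrients <- function(applications, products) {
  if (nrow(applications) == 0) return(c(n = 0, p = 0, k = 0))
  idx <- match(applications$product, products$name)
  if (anyNA(idx))
    stop_input("unknown product name: ",
               paste(unique(applications$product[is.na(idx)]),
                     collapse = ", "))
  frac <- elemental_fractions(products)[idx, , drop = FALSE]
  c(n = sum(applications$amount_kg_ha * frac[, "n"]),
    p = sum(applications$amount_kg_ha * frac[, "p"]),
    k = sum(applications$amount_kg_ha * frac[, "k"]))
}

#' Total fertilizer cost of an allocation
#'
#' TFC is the sum over all applications of amount times the product's
#' farmgate price.
#'
#' @param allocation a [allocate_products()] result, or any data.frame
#'   of applications with `product` and `amount_kg_ha`
#' @param products product table with `price_usd_per_kg`
#' @return US$ per ha
#' @export
total_fertilizer_cost <- function(allocation, products) {
  apps <- if (inherits(allocation, "product_allocation"))
    allocation$applications else allocation
  if (nrow(apps) == 0) return(0)
  idx <- match(apps$product, products$name)
  if (anyNA(idx))
    stop_input("no price for product(s): ",
               paste(unique(apps$product[is.na(idx)]), collapse = ", "))
  price <- products$price_usd_per_kg[idx]
  if (anyNA(price)) stop_input("missing price in product table")
  sum(apps$amount_kg_ha * price)
}

#' @export
print.product_allocation <- function(x, ...) {
  cat("Product allocation\n")
  if (nrow(x$applications) == 0) cat("  (no applications)\n")
  for (i in seq_len(nrow(x$applications)))
    cat(sprintf("  %-18s %3d DAT  %-14s %7.1f kg/ha\n",
                x$applications$stage[i], x$applications$dat[i],
                x$applications$product[i], x$applications$amount_kg_ha[i]))
  cat(sprintf("  delivered N/P/K: %.1f / %.1f / %.1f kg/ha\n",
              x$delivered["n"], x$delivered["p"], x$delivered["k"]))
  if (any(x$unmet > 0))
    cat(sprintf("  UNMET N/P/K: %.1f / %.1f / %.1f kg/ha\n",
                x$unmet["n"], x$unmet["p"], x$unmet["k"]))
  invisible(x)
}
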