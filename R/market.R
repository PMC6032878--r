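#' Create a world market state
#'
#' One world price per commodity; stocks buffer over- and undersupply, and
#' prices adjust exponentially against relative oversupply each settlement
#' (supply and demand need not be in equilibrium in any year).
#'
#' @param prices named vector of initial prices ($/t), all > 0.
#' @param stocks named vector of initial stock levels (t); defaults to zero.
#' @param lambda price adjustment rate (> 0).
#' @return object of class `market_state`.
#' @export
market_state <- function(prices, stocks = NULL, lambda = 0.05) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (any(prices <= 0)) stop("prices must be > 0", call. = FALSE)
  if (is.null(stocks)) stocks <- setNames(rep(0, length(prices)),
                                          names(prices))
  stocks <- stocks[names(prices)]
  stocks[is.na(stocks)] <- 0
  names(stocks) <- names(prices)
  if (any(stocks < 0)) stop("stocks must be >= 0", call. = FALSE)
  structure(list(prices = prices, stocks = stocks, lambda = lambda,
                 last_flows = NULL),
            class = "market_state")
}

#' @export
print.market_state <- function(x, ...) {
  df <- data.frame(commodity = names(x$prices),
                   price = as.numeric(x$prices),
                   stock = as.numeric(x$stocks[names(x$prices)]))
  cat("Market state (lambda =", x$lambda, ")\n")
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Settle the world market for one year
#'
#' Aggregates country exports and imports, adds second-generation energy
#' demand on the demand side, computes per-commodity oversupply
#' `O = exports - imports - secondgen_demand` (energy-crop production enters
#' through exports), accumulates it into stocks floored at zero (shortfall
#' beyond stocks is recorded as unmet), and adjusts prices exponentially on
#' relative oversupply: `p' = p exp(-lambda O / max(imports + secondgen,
#' eps))`, so price moves opposite to the sign of the imbalance.
#'
#' @param state a `market_state`.
#' @param solutions list of `country_solution` objects for the year.
#' @param secondgen_demand_t global second-generation energy-crop demand (t),
#'   attributed to the `energy_crops` commodity.
#' @param eps floor on the relative-oversupply denominator (t); defaults to
#'   a tenth of each commodity's gross traded volume so the relative
#'   imbalance stays bounded when one trade side is empty.
#' @param max_log_step bound on `|lambda O / denom|` per settlement: caps
#'   the price change at `exp(max_log_step)`-fold per year while preserving
#'   its direction (numerical safeguard, not a market mechanism).
#' @return the next `market_state`; its `last_flows` element records
#'   per-commodity exports, imports, oversupply, stock change and unmet
#'   demand.
#' @export
settle_market <- function(state, solutions, secondgen_demand_t = 0,
                          eps = NULL, max_log_step = 1) {
  stopifnot(inherits(state, "market_state"))
  comms <- names(state$prices)
  ex <- setNames(numeric(length(comms)), comms)
  im <- ex
  for (s in solutions) {
    tr <- s$trade
    i <- match(tr$commodity, comms)
    ok <- !is.na(i)
    ex[i[ok]] <- ex[i[ok]] + tr$exports_t[ok]
    im[i[ok]] <- im[i[ok]] + tr$imports_t[ok]
  }
  dem2 <- setNames(rep(0, length(comms)), comms)
  if ("energy_crops" %in% comms)
    dem2["energy_crops"] <- secondgen_demand_t

  O <- ex - im - dem2
  new_stock <- state$stocks + O
  unmet <- pmax(-new_stock, 0)
  new_stock <- pmax(new_stock, 0)
  if (is.null(eps)) eps <- pmax(1, 0.1 * (ex + im + dem2))
  denom <- pmax(im + dem2, eps)
  step <- pmin(pmax(-state$lambda * O / denom, -max_log_step), max_log_step)
  new_price <- state$prices * exp(step)

  flows <- data.frame(commodity = comms, exports_t = as.numeric(ex),
                      imports_t = as.numeric(im),
                      secondgen_t = as.numeric(dem2),
                      oversupply_t = as.numeric(O),
                      stock_t = as.numeric(new_stock),
                      unmet_t = as.numeric(unmet),
                      price = as.numeric(new_price))
  out <- state
  out$prices <- new_price
  out$stocks <- new_stock
  out$last_flows <- flows
  out
}

#' Import price inflation
#'
#' Import unit cost is the world price inflated by tariff, transport and
#' in-transit loss rates: `price * (1 + tariff + transport + loss)`.
#' Export revenue per tonne is the uninflated world price, so the import
#' price never falls below export revenue.
#'
#' @param price world price, $/t.
#' @param tariff,transport,loss non-negative rates (fractions of price).
#' @return inflated import price, $/t.
#' @examples
#' import_price(100, 0.1, 0.05, 0.05)  # 120
#' @export
import_price <- function(price, tariff, transport, loss) {
  if (any(c(tariff, transport, loss) < 0))
    stop("rates must be >= 0", call. = FALSE)
  price * (1 + tariff + transport + loss)
}
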