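#' Scenario configuration for the synthetic notification generator
#'
#' Describes a synthetic surveillance scenario: which countries take part,
#' how intensely each reports (detect rate) and is reported against
#' (transgress rate), the date range, the contamination-category mixture and
#' the notification-type mixture. The defaults emulate the published
#' structure of the EU food/feed alert stream: detectors restricted to EU
#' member states (non-EU countries appear only as transgressors), a
#' category mixture matching the observed proportions of categorized
#' notifications (mycotoxin 50.45%, bacteria 20.26%, metal 10.95%, chemical
#' 15.54%, other 2.80%), and a realistic share of records whose hazard text
#' matches no category keyword.
#'
#' @param countries `data.frame` with columns `country`, `detect_rate`,
#'   `transgress_rate` (non-negative; a zero detect rate makes a country a
#'   pure transgressor).
#' @param date_range Length-2 date vector (start, end).
#' @param n_notifications Number of records to generate.
#' @param category_mix Named probability vector over the keyword-table
#'   categories; must sum to 1.
#' @param uncategorized_prob Probability that a record's hazard text matches
#'   no keyword (a labelling issue, foreign body etc.). Default 0.396.
#' @param border_rejection_prob Probability a record is a border rejection;
#'   the remainder is split evenly between alerts and information notices.
#' @param rate_change_events Optional list of interventions, each
#'   `list(country=, date=, transgress_rate=)`: from `date` on, the
#'   country's transgress rate changes to the new value (e.g. remediation
#'   dropping it to 0).
#' @param allow_self_reports Permit detector == transgressor draws.
#' @param seed Integer seed; the generator is fully reproducible given the
#'   config.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(countries,
                            date_range = c("2003-05-01", "2008-08-31"),
                            n_notifications = 15000L,
                            category_mix = c(mycotoxin = 0.5045,
                                             bacteria = 0.2026,
                                             metal = 0.1095,
                                             chemical = 0.1554,
                                             other = 0.0280),
                            uncategorized_prob = 0.396,
                            border_rejection_prob = 0.25,
                            rate_change_events = list(),
                            allow_self_reports = FALSE,
                            seed = 1L) {
  stopifnot(is.data.frame(countries),
            all(c("country", "detect_rate", "transgress_rate") %in%
                  names(countries)))
  if (any(countries$detect_rate < 0) || any(countries$transgress_rate < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  if (sum(countries$detect_rate) <= 0 || sum(countries$transgress_rate) <= 0) {
    stop("infeasible scenario: need at least one positive detect rate and ",
         "one positive transgress rate", call. = FALSE)
  }
  if (nrow(countries) < 2L) stop("need at least two countries", call. = FALSE)
  date_range <- parse_iso_date(date_range)
  stopifnot(length(date_range) == 2L, date_range[1] <= date_range[2])
  n_notifications <- as.integer(n_notifications)
  if (is.na(n_notifications) || n_notifications <= 0L) {
    stop("n_notifications must be a positive integer", call. = FALSE)
  }
  if (abs(sum(category_mix) - 1) > 1e-8) {
    stop("category_mix must sum to 1", call. = FALSE)
  }
  stopifnot(uncategorized_prob >= 0, uncategorized_prob <= 1,
            border_rejection_prob >= 0, border_rejection_prob <= 1)
  for (ev in rate_change_events) {
    stopifnot(all(c("country", "date", "transgress_rate") %in% names(ev)))
    if (!ev$country %in% countries$country) {
      stop("rate_change_event for unknown country ", ev$country, call. = FALSE)
    }
  }
  structure(
    list(countries = countries, date_range = date_range,
         n_notifications = n_notifications, category_mix = category_mix,
         uncategorized_prob = uncategorized_prob,
         border_rejection_prob = border_rejection_prob,
         rate_change_events = rate_change_events,
         allow_self_reports = allow_self_reports, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Default RASFF-like scenario
#'
#' Ten EU member states with both detector and (smaller) transgressor
#' activity plus six non-EU pure transgressors, over the May 2003 - August
#' 2008 window. Rates are stylized: one dominant detector (DEU) with strong
#' contributions from ITA and ESP, and a dominant mycotoxin-era transgressor
#' (IRN) followed by CHN.
#'
#' @param ... Overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
default_scenario <- function(...) {
  countries <- data.frame(
    country = c("DEU", "ITA", "ESP", "FRA", "GBR", "NLD", "POL", "DNK",
                "FIN", "SWE", "IRN", "CHN", "TUR", "BRA", "IND", "ARG"),
    detect_rate = c(3.0, 2.5, 2.0, 1.5, 1.5, 1.2, 0.8, 0.5,
                    0.4, 0.6, 0, 0, 0, 0, 0, 0),
    transgress_rate = c(0.6, 0.5, 0.8, 0.4, 0.3, 0.4, 0.3, 0.1,
                        0.1, 0.1, 3.0, 2.0, 1.5, 1.2, 1.2, 0.8),
    stringsAsFactors = FALSE
  )
  scenario_config(countries, ...)
}

#' Read a scenario configuration from a YAML file
#'
#' The file carries the [scenario_config()] fields; `countries` is a list of
#' `{country, detect_rate, transgress_rate}` maps and `rate_change_events`
#' (optional) a list of `{country, date, transgress_rate}` maps.
#'
#' @param path YAML file path.
#' @return A `scenario_config`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$countries))
  countries <- do.call(rbind, lapply(cfg$countries, function(x) {
    data.frame(country = x$country,
               detect_rate = as.numeric(x$detect_rate),
               transgress_rate = as.numeric(x$transgress_rate),
               stringsAsFactors = FALSE)
  }))
  args <- cfg[setdiff(names(cfg), "countries")]
  if (!is.null(args$category_mix)) args$category_mix <- unlist(args$category_mix)
  if (!is.null(args$date_range)) args$date_range <- unlist(args$date_range)
  do.call(scenario_config, c(list(countries = countries), args))
}

# hazard phrasings: a category keyword embedded in a plausible product line
hazard_phrase <- function(category, table, foods) {
  kw <- vapply(table[category], function(k) sample(k, 1L), character(1))
  paste0(kw, " in ", sample(foods, length(kw), replace = TRUE))
}

UNCATEGORIZED_HAZARDS <- c(
  "incorrect labelling of allergens", "undeclared gluten",
  "foreign body (glass fragments)", "spoilage and off-odour",
  "damaged packaging", "unauthorised novel food ingredient",
  "too high content of colour E 110", "mould growth"
)

GENERATOR_FOODS <- c(
  "pistachio kernels", "frozen squid", "peanut butter", "dried figs",
  "paprika powder", "poultry meat", "rice noodles", "sunflower oil",
  "black tea", "smoked salmon", "maize flour", "chilled mussels"
)

#' Generate a synthetic notification log
#'
#' Draws `n_notifications` records under a [scenario_config()]: dates
#' uniform over the range; detector sampled proportional to detect rates;
#' transgressor sampled proportional to the transgress rates in force at the
#' record's date (interventions in `rate_change_events` modulate a country's
#' rate from their date onward); hazard text built from a keyword of the
#' drawn category (or an uncategorized phrase); notification type drawn from
#' the type mixture. Fully reproducible under the config seed.
#'
#' @param config A `scenario_config`.
#' @param keyword_table Keyword table supplying category vocabularies.
#' @return A [notification_log()] sorted by date.
#' @export
generate_log <- function(config, keyword_table = rasff_keywords()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_notifications
  cn <- config$countries
  dates <- config$date_range[1] +
    sample.int(as.integer(diff(config$date_range)) + 1L, n, replace = TRUE) - 1L
  dates <- sort(dates)
  detector <- sample(cn$country, n, replace = TRUE, prob = cn$detect_rate)

  # transgress rates are piecewise-constant in time: build one rate table per
  # regime delimited by the intervention dates, then sample within regimes
  ev_dates <- sort(unique(parse_iso_date(
    vapply(config$rate_change_events, function(e) as.character(e$date), ""))))
  breaks <- c(as.Date("0001-01-01"), ev_dates, as.Date("9999-12-31"))
  regime <- findInterval(dates, breaks)
  transgressor <- character(n)
  events <- config$rate_change_events
  if (length(events)) {
    events <- events[order(vapply(events, function(e) as.character(e$date),
                                  ""))]
  }
  for (r in unique(regime)) {
    rates <- stats::setNames(cn$transgress_rate, cn$country)
    for (ev in events) {
      if (parse_iso_date(ev$date) < breaks[r + 1L]) {
        rates[ev$country] <- ev$transgress_rate
      }
    }
    idx <- which(regime == r)
    if (sum(rates) <= 0) {
      stop("all transgress rates are zero from ", format(breaks[r]),
           call. = FALSE)
    }
    transgressor[idx] <- sample(cn$country, length(idx), replace = TRUE,
                                prob = rates)
    if (!config$allow_self_reports) {
      same <- idx[transgressor[idx] == detector[idx]]
      guard <- 0L
      while (length(same)) {
        transgressor[same] <- sample(cn$country, length(same), replace = TRUE,
                                     prob = rates)
        same <- same[transgressor[same] == detector[same]]
        guard <- guard + 1L
        if (guard > 1000L) {
          stop("cannot avoid self-reports under this configuration",
               call. = FALSE)
        }
      }
    }
  }

  uncat <- stats::runif(n) < config$uncategorized_prob
  category <- rep(NA_character_, n)
  category[!uncat] <- sample(names(config$category_mix), sum(!uncat),
                             replace = TRUE, prob = config$category_mix)
  hazard <- character(n)
  hazard[uncat] <- sample(UNCATEGORIZED_HAZARDS, sum(uncat), replace = TRUE)
  if (any(!uncat)) {
    hazard[!uncat] <- hazard_phrase(category[!uncat], keyword_table,
                                    GENERATOR_FOODS)
  }

  u <- stats::runif(n)
  type <- ifelse(u < config$border_rejection_prob, "border_rejection",
                 ifelse(u < config$border_rejection_prob +
                          (1 - config$border_rejection_prob) / 2,
                        "alert", "information"))

  notification_log(dates, detector, transgressor, type, hazard,
                   provenance = paste0("synthetic scenario (seed ",
                                       config$seed, ")"),
                   keyword_table = keyword_table)
}
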