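#' Body surface area of the representative patient
#'
#' Linear Chinese-population formula:
#' `BSA (m^2) = 0.0061 height(cm) + 0.0128 weight(kg) - 0.1529`.
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @return Body surface area in square metres.
#' @examples
#' body_surface_area(158, 59)   # 1.5661
#' @export
body_surface_area <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  bsa <- 0.0061 * height_cm + 0.0128 * weight_kg - 0.1529
  if (any(bsa <= 0)) {
    stop("formula yields non-positive body surface area", call. = FALSE)
  }
  bsa
}

#' Chemotherapy drug specification
#'
#' @param name Drug name.
#' @param vial_content_mg Milligrams per vial (> 0).
#' @param unit_price Yuan per vial (>= 0).
#' @param dose_per_bsa Dose in mg per square metre of body surface area.
#' @param administrations_per_cycle Administrations per 21-day cycle.
#' @return An object of class `"drug_spec"`.
#' @export
drug_spec <- function(name, vial_content_mg, unit_price, dose_per_bsa,
                      administrations_per_cycle = 1) {
  if (vial_content_mg <= 0) stop("`vial_content_mg` must be > 0",
                                 call. = FALSE)
  if (unit_price < 0) stop("`unit_price` must be >= 0", call. = FALSE)
  structure(list(name = name, vial_content_mg = vial_content_mg,
                 unit_price = unit_price, dose_per_bsa = dose_per_bsa,
                 administrations_per_cycle = administrations_per_cycle),
            class = "drug_spec")
}

#' Chemotherapy regimen definition
#'
#' A regimen is the unit the decision model costs: BSA-dosed drugs,
#' fixed-count concomitant medications, and per-cycle adverse-event
#' management, administration and laboratory-testing components, all
#' repeated over `n_cycles` 21-day cycles.
#'
#' @param name Regimen label, e.g. `"TC"`.
#' @param drugs List of [drug_spec()] objects.
#' @param flat_items Named numeric vector: per-cycle price of items with
#'   fixed vial counts (antiemetics, G-CSF, ...).
#' @param ae_management_cost,administration_cost,testing_cost Yuan per
#'   cycle.
#' @param n_cycles Number of cycles (default 4).
#' @param cycle_length_days Cycle length (default 21; informational).
#' @return An object of class `"regimen"`.
#' @export
regimen <- function(name, drugs, flat_items = numeric(0),
                    ae_management_cost = 0, administration_cost = 0,
                    testing_cost = 0, n_cycles = 4,
                    cycle_length_days = 21) {
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  stopifnot(all(vapply(drugs, inherits, logical(1), "drug_spec")))
  costs <- c(unlist(flat_items), ae_management_cost, administration_cost,
             testing_cost)
  if (any(costs < 0)) stop("costs must be non-negative", call. = FALSE)
  structure(list(name = name, drugs = drugs, flat_items = flat_items,
                 ae_management_cost = ae_management_cost,
                 administration_cost = administration_cost,
                 testing_cost = testing_cost, n_cycles = n_cycles,
                 cycle_length_days = cycle_length_days),
            class = "regimen")
}

#' Required dose of a drug for a given body surface area
#'
#' @param drug A [drug_spec()].
#' @param bsa Body surface area in m^2.
#' @return Dose in mg per administration.
#' @export
required_dose <- function(drug, bsa) {
  stopifnot(inherits(drug, "drug_spec"))
  drug$dose_per_bsa * bsa
}

#' Vials needed per cycle (ceiling rounding, no vial sharing)
#'
#' @param dose_mg Required dose per administration.
#' @param vial_content_mg Vial content in mg.
#' @param administrations_per_cycle Administrations per cycle.
#' @return Integer vial count per cycle.
#' @export
vials_per_cycle <- function(dose_mg, vial_content_mg,
                            administrations_per_cycle = 1) {
  if (dose_mg < 0) stop("`dose_mg` must be >= 0", call. = FALSE)
  as.integer(ceiling(dose_mg / vial_content_mg) *
               administrations_per_cycle)
}

#' Full course cost of a regimen
#'
#' Per-cycle drug prices are vial counts times unit prices; flat
#' concomitants, adverse-event management, administration and testing are
#' added per cycle; everything is multiplied by the number of cycles.
#'
#' @param reg A [regimen()].
#' @param bsa Body surface area in m^2.
#' @return An object of class `"cost_breakdown"`: list with `drugs` (data
#'   frame: name, dose_mg, vials, price_per_cycle, course_price),
#'   `components` (named course totals), `per_cycle_total` and
#'   `grand_total` (yuan).
#' @examples
#' course_cost(regimen_tc(), body_surface_area(158, 59))$grand_total
#' @export
course_cost <- function(reg, bsa) {
  stopifnot(inherits(reg, "regimen"))
  if (bsa <= 0) stop("`bsa` must be positive", call. = FALSE)
  drugs <- do.call(rbind, lapply(reg$drugs, function(d) {
    dose <- required_dose(d, bsa)
    vials <- vials_per_cycle(dose, d$vial_content_mg,
                             d$administrations_per_cycle)
    per_cycle <- vials * d$unit_price
    data.frame(name = d$name, dose_mg = dose, vials = vials,
               price_per_cycle = per_cycle,
               course_price = per_cycle * reg$n_cycles)
  }))
  flat_cycle <- sum(unlist(reg$flat_items))
  components <- c(
    drugs = sum(drugs$course_price),
    concomitant = flat_cycle * reg$n_cycles,
    ae_management = reg$ae_management_cost * reg$n_cycles,
    administration = reg$administration_cost * reg$n_cycles,
    testing = reg$testing_cost * reg$n_cycles
  )
  per_cycle_total <- sum(drugs$price_per_cycle) + flat_cycle +
    reg$ae_management_cost + reg$administration_cost + reg$testing_cost
  structure(
    list(regimen = reg$name, bsa = bsa, drugs = drugs,
         components = components, per_cycle_total = per_cycle_total,
         grand_total = sum(components)),
    class = "cost_breakdown"
  )
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown>", x$regimen, "regimen, BSA", format(x$bsa),
      "m^2\n")
  print(x$drugs, row.names = FALSE)
  cat("course components (yuan):\n")
  print(round(x$components, 2))
  cat("grand total:", format(x$grand_total, nsmall = 2), "yuan\n")
  invisible(x)
}

#' Built-in regimens at 2022 Chinese list prices
#'
#' `regimen_tc()` is the taxane + cyclophosphamide standard-of-care course
#' (4 cycles); `regimen_act()` the anthracycline + cyclophosphamide +
#' taxane course used for higher-risk patients.  Unit prices can be
#' overridden, which is how the sensitivity analyses perturb them.
#'
#' @param prices Named list of unit prices (yuan per vial / pack):
#'   `docetaxel`, `epirubicin`, `cyclophosphamide`, `palonosetron`,
#'   `aprepitant`, `dexamethasone`, `gcsf`.
#' @param ae_cost,admin_cost,testing_cost Per-cycle components (yuan).
#' @return A [regimen()].
#' @name builtin_regimens
#' @export
regimen_tc <- function(prices = default_unit_prices(), ae_cost = 9201,
                       admin_cost = 2400, testing_cost = 1005.04) {
  regimen(
    name = "TC",
    drugs = list(
      drug_spec("docetaxel", 20, prices$docetaxel, dose_per_bsa = 75),
      drug_spec("cyclophosphamide", 200, prices$cyclophosphamide,
                dose_per_bsa = 600)
    ),
    flat_items = c(palonosetron = prices$palonosetron,
                   dexamethasone = 2 * prices$dexamethasone,
                   gcsf = prices$gcsf),
    ae_management_cost = ae_cost, administration_cost = admin_cost,
    testing_cost = testing_cost
  )
}

#' @rdname builtin_regimens
#' @export
regimen_act <- function(prices = default_unit_prices(), ae_cost = 21175,
                        admin_cost = 3200, testing_cost = 1002) {
  regimen(
    name = "AC-T",
    drugs = list(
      drug_spec("epirubicin", 10, prices$epirubicin, dose_per_bsa = 100),
      drug_spec("docetaxel", 20, prices$docetaxel, dose_per_bsa = 80),
      drug_spec("cyclophosphamide", 200, prices$cyclophosphamide,
                dose_per_bsa = 600)
    ),
    flat_items = c(palonosetron = prices$palonosetron,
                   aprepitant = prices$aprepitant,
                   dexamethasone = 2 * prices$dexamethasone,
                   gcsf = prices$gcsf),
    ae_management_cost = ae_cost, administration_cost = admin_cost,
    testing_cost = testing_cost
  )
}

#' @rdname builtin_regimens
#' @export
default_unit_prices <- function() {
  list(docetaxel = 139.28, epirubicin = 79.15, cyclophosphamide = 23.98,
       palonosetron = 53.8, aprepitant = 450, dexamethasone = 0.58,
       gcsf = 58.98)
}
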