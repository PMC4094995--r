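#' Candidate cost scheme
#'
#' Costs express how plausible a candidate reaction is for the organism: the
#' LP penalises candidate flux by `c_r`, so cheaper reactions are preferred.
#' A spontaneous (non-enzymatic) reaction can occur in any organism and gets
#' the lowest cost; enzymatic candidates are costed by taxonomic range, with
#' reactions outside the organism's range costed highest. `biomass_gain` is
#' used only by the soft-biomass variant of the MILP oracle. Only the
#' relative magnitudes of these weights matter, not their absolute values.
#'
#' The default scheme is 1 (spontaneous), 5 (in range), 10 (unknown range),
#' 15 (out of range), with a biomass gain of 500 — a gain-to-in-range-cost
#' ratio of 100.
#'
#' @param spontaneous_cost,in_range_cost,unknown_range_cost,out_of_range_cost
#'   Non-negative costs, required to be monotone in that order.
#' @param biomass_gain Positive gain per biomass metabolite (MILP oracle
#'   soft-biomass variant only).
#' @return An object of class `fgf_cost_scheme`.
#' @export
cost_scheme <- function(spontaneous_cost = 1, in_range_cost = 5,
                        unknown_range_cost = 10, out_of_range_cost = 15,
                        biomass_gain = 500) {
  vals <- c(spontaneous_cost, in_range_cost, unknown_range_cost,
            out_of_range_cost)
  if (any(vals < 0))
    stop("costs must be non-negative")
  if (is.unsorted(vals))
    stop("costs must satisfy spontaneous <= in_range <= unknown <= out_of_range")
  if (biomass_gain <= 0)
    stop("biomass_gain must be positive")
  structure(list(spontaneous_cost = spontaneous_cost,
                 in_range_cost = in_range_cost,
                 unknown_range_cost = unknown_range_cost,
                 out_of_range_cost = out_of_range_cost,
                 biomass_gain = biomass_gain),
            class = "fgf_cost_scheme")
}

#' Default cost scheme
#' @return The default [cost_scheme()] (1/5/10/15, gain 500).
#' @export
default_cost_scheme <- function() cost_scheme()

#' Read a cost scheme from a JSON config file
#'
#' The file holds any subset of the five scheme values; omitted values take
#' their defaults.
#'
#' @param path Path to a JSON file, e.g. `{"in_range_cost": 5}`.
#' @return An `fgf_cost_scheme`.
#' @export
read_cost_scheme <- function(path) {
  j <- jsonlite::read_json(path)
  do.call(cost_scheme, j[intersect(names(j), names(formals(cost_scheme)))])
}

#' Assign default costs to a candidate pool
#'
#' Fills every unassigned (`NA`) cost from the scheme: spontaneous reactions
#' get `spontaneous_cost` regardless of taxonomic status; enzymatic reactions
#' are costed by taxonomic status. Candidates with explicit costs are left
#' untouched, so the operation is idempotent.
#'
#' @param pool An `fgf_pool`.
#' @param scheme An `fgf_cost_scheme` (default [default_cost_scheme()]).
#' @return The pool with all costs assigned.
#' @export
assign_costs <- function(pool, scheme = default_cost_scheme()) {
  stopifnot(inherits(scheme, "fgf_cost_scheme"))
  for (id in names(pool$candidates)) {
    if (!is.na(pool$costs[[id]])) next
    r <- pool$candidates[[id]]
    pool$costs[[id]] <- switch(
      r$kind,
      spontaneous = scheme$spontaneous_cost,
      enzymatic = switch(
        r$taxonomic_status,
        in_range = scheme$in_range_cost,
        unknown = scheme$unknown_range_cost,
        out_of_range = scheme$out_of_range_cost,
        stop("enzymatic candidate '", id,
             "' requires a taxonomic_status (in_range/unknown/out_of_range), got '",
             r$taxonomic_status, "'")),
      stop("cannot assign a default cost to candidate '", id,
           "' of kind '", r$kind, "'"))
  }
  pool
}
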