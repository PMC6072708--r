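#' Segregation rule
#'
#' Encodes the family design the carrier pattern must match: individuals in
#' `required_carrier_roles` must carry the variant (het or hom_alt, a
#' dominant-model carrier definition), individuals in
#' `forbidden_carrier_roles` must not. The integer tolerances relax the rule:
#' up to `max_noncarrier_cases` required-role individuals may fail to carry,
#' and up to `max_carrier_controls` forbidden-role individuals may carry.
#' With the strict defaults (0/0) every case must carry and no control or
#' exclusion case may.
#'
#' @param required_carrier_roles roles that must carry (default `case`).
#' @param forbidden_carrier_roles roles that must not carry (default
#'   `control` and `exclusion_case`).
#' @param max_noncarrier_cases tolerated non-carrying (or missing) cases.
#' @param max_carrier_controls tolerated carriers among forbidden roles.
#' @return a `segregation_rule`.
#' @export
segregation_rule <- function(required_carrier_roles = "case",
                             forbidden_carrier_roles = c("control",
                                                         "exclusion_case"),
                             max_noncarrier_cases = 0,
                             max_carrier_controls = 0) {
  if (length(intersect(required_carrier_roles,
                       forbidden_carrier_roles)) > 0) {
    stop("required and forbidden role sets must be disjoint", call. = FALSE)
  }
  if (max_noncarrier_cases < 0 || max_carrier_controls < 0) {
    stop("segregation tolerances must be >= 0", call. = FALSE)
  }
  structure(list(required_carrier_roles = required_carrier_roles,
                 forbidden_carrier_roles = forbidden_carrier_roles,
                 max_noncarrier_cases = as.integer(max_noncarrier_cases),
                 max_carrier_controls = as.integer(max_carrier_controls)),
            class = "segregation_rule")
}

#' Pedigree segregation filter
#'
#' The hallmark stage of the funnel: a variant survives iff its carrier
#' pattern matches the family design. Carrying means a het or hom_alt call.
#' A missing call at a required-carrier sample counts as non-carrying, so
#' under the strict default tolerances a missing case call removes the
#' variant; in addition at least one required-role individual must actually
#' carry, so a variant can never pass vacuously (e.g. with all calls
#' missing) however the tolerances are relaxed. Surviving records are
#' annotated with `n_cases_carrying` and `n_unknown_carrying`.
#'
#' @param variants a `variant_table`.
#' @param pedigree a `pedigree`; must contain at least one required-role
#'   individual.
#' @param rule a [segregation_rule()] (default: strict).
#' @return the surviving `variant_table` with carrier-count columns.
#' @export
segregate <- function(variants, pedigree, rule = segregation_rule()) {
  stopifnot(inherits(rule, "segregation_rule"))
  req_ids <- pedigree_roles(pedigree, rule$required_carrier_roles)
  forb_ids <- pedigree_roles(pedigree, rule$forbidden_carrier_roles)
  unk_ids <- pedigree_roles(pedigree, "unknown")
  if (length(req_ids) == 0) {
    stop("pedigree has no individual in a required-carrier role",
         call. = FALSE)
  }
  absent <- setdiff(c(req_ids, forb_ids, unk_ids), samples(variants))
  if (length(absent) > 0) {
    stop("pedigree sample(s) absent from variant table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  carry_count <- function(ids) {
    if (length(ids) == 0 || nrow(variants) == 0) {
      return(integer(nrow(variants)))
    }
    gt <- as.matrix(
      as.data.frame(variants)[, paste0("gt_", ids), drop = FALSE])
    as.integer(rowSums(gt == "het" | gt == "hom_alt"))
  }
  n_req_carrying <- carry_count(req_ids)
  n_forb_carrying <- carry_count(forb_ids)
  n_unknown_carrying <- carry_count(unk_ids)
  keep <- n_req_carrying >= 1 &
    (length(req_ids) - n_req_carrying) <= rule$max_noncarrier_cases &
    n_forb_carrying <= rule$max_carrier_controls
  out <- variants
  out$n_cases_carrying <- n_req_carrying
  out$n_unknown_carrying <- n_unknown_carrying
  restore_variant_table(out[keep, , drop = FALSE], samples(variants))
}

#' Funnel stage percentage
#'
#' Percentage of variants surviving a stage, half-up rounded to one decimal.
#'
#' @param n_before,n_after counts before and after the stage;
#'   `n_before` must be positive and `n_after` between 0 and `n_before`.
#' @return `100 * n_after / n_before`, rounded half-up to 1 decimal.
#' @export
funnel_fraction <- function(n_before, n_after) {
  if (any(n_before <= 0)) {
    stop("funnel fraction undefined for n_before = 0", call. = FALSE)
  }
  if (any(n_after < 0 | n_after > n_before)) {
    stop("n_after must lie in [0, n_before]", call. = FALSE)
  }
  round_half_up(100 * n_after / n_before, 1)
}
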