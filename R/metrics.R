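#' Positioning of vulnerable individuals within their group
#'
#' Vulnerable individuals are mothers (any adult with an attached pouch
#' young or young-at-foot), young-at-foot and pouch young. For each, the
#' individual distance to cover (IDC) and the group-centre distance to
#' cover (GDC) are measured; `delta = GDC - IDC` is positive when the
#' individual sits closer to the forest edge than the group centre
#' ("front"), negative when further ("behind"). Exact ties (`delta = 0`,
#' e.g. a pouch young and its mother at the group centre) are assigned
#' "behind" so the front proportion is never inflated. Groups are the
#' 15 m chain-rule partition unless another chain is given.
#'
#' @param observations Observation table (any number of sessions).
#' @param landscape A `"mob_landscape"`.
#' @param chain Chain distance used to form groups (m); 15 by default.
#' @return Data frame of positioning records: session, zone, group, id,
#'   demo_class, idc, gdc, delta, side ("front"/"behind"), bracket (lower
#'   edge of the group's 20 m distance-from-cover bin).
#' @export
classify_positioning <- function(observations, landscape, chain = 15) {
  recs <- list()
  for (s in sort(unique(observations$session))) {
    obs_s <- observations[observations$session == s, , drop = FALSE]
    part <- assign_groups(obs_s, chain)
    if (!nrow(part$assignment)) next
    obs_s$group <- part$assignment$group[match(as.character(obs_s$id),
                                               part$assignment$id)]
    obs_s <- obs_s[!is.na(obs_s$group), , drop = FALSE]
    mothers <- unique(stats::na.omit(as.character(obs_s$mother_id)))
    vulnerable <- obs_s$demo_class %in% c("YAF", "PY") |
      as.character(obs_s$id) %in% mothers
    for (g in unique(obs_s$group)) {
      gm <- obs_s[obs_s$group == g, , drop = FALSE]
      ctr <- group_centroid(gm)
      zone <- zone_of(ctr[1], ctr[2], landscape)
      gdc <- distance_to_cover(ctr[1], ctr[2], landscape, zone = zone)
      vm <- gm[vulnerable[obs_s$group == g], , drop = FALSE]
      if (!nrow(vm)) next
      idc <- distance_to_cover(vm$x_m, vm$y_m, landscape, zone = zone)
      delta <- gdc - idc
      recs[[length(recs) + 1L]] <- data.frame(
        session = s, zone = zone, group = g, id = as.character(vm$id),
        demo_class = vm$demo_class, idc = idc, gdc = gdc, delta = delta,
        side = ifelse(delta > 0, "front", "behind"),
        bracket = 20 * floor(gdc / 20),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(session = integer(), zone = character(),
                      group = integer(), id = character(),
                      demo_class = character(), idc = numeric(),
                      gdc = numeric(), delta = numeric(), side = character(),
                      bracket = numeric()))
  do.call(rbind, recs)
}

#' Front proportions by zone and distance bracket
#'
#' @param records Positioning records from [classify_positioning()].
#' @param bracket_width Width of the distance-from-cover bins (m).
#' @return Data frame (zone, bracket, n, prop_front); empty brackets are
#'   omitted.
#' @export
positioning_proportions <- function(records, bracket_width = 20) {
  if (!nrow(records)) stop("no positioning records")
  records$bracket <- bracket_width * floor(records$gdc / bracket_width)
  agg <- stats::aggregate(cbind(n = rep(1, nrow(records)),
                                front = records$side == "front"),
                          by = list(zone = records$zone,
                                    bracket = records$bracket), FUN = sum)
  agg$prop_front <- agg$front / agg$n
  agg$front <- NULL
  agg[order(agg$zone, agg$bracket), ]
}

#' Grazing density per zone and session
#'
#' Individuals surveyed per square kilometre of cleared habitat. All
#' out-of-pouch individuals count, including those disturbed during the
#' survey; zones surveyed but empty in a session get density 0.
#'
#' @param observations Observation table.
#' @param landscape A `"mob_landscape"` (supplies zone areas).
#' @return Data frame (zone, session, n, density_km2).
#' @export
grazing_density <- function(observations, landscape) {
  zones <- landscape$zones
  if (any(zones$area_ha <= 0)) stop("zone with non-positive cleared area")
  sessions <- sort(unique(observations$session))
  grid <- expand.grid(zone = zones$zone, session = sessions,
                      stringsAsFactors = FALSE)
  obs <- observations[observations$in_pouch == 0L, , drop = FALSE]
  cnt <- stats::aggregate(list(n = obs$id),
                          by = list(zone = obs$zone, session = obs$session),
                          FUN = length)
  out <- merge(grid, cnt, all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  out$density_km2 <- out$n / (zones$area_ha[match(out$zone, zones$zone)] / 100)
  out[order(out$zone, out$session), ]
}

#' Relative green channel brightness (greenness)
#'
#' Total brightness is the sum of the three colour channels over all pixels
#' of the region of interest; greenness is the summed green channel divided
#' by that total. The index is invariant to uniform rescaling of all
#' channels, so 8-bit (0..255) and unit-range arrays give identical values.
#'
#' @param sample A `"greenness_patch"` or any h x w x 3 numeric array.
#' @return Greenness fraction in `[0, 1]`.
#' @export
greenness <- function(sample) {
  a <- unclass(sample)
  if (length(dim(a)) != 3 || dim(a)[3] != 3)
    stop("sample must be an h x w x 3 RGB array")
  tot <- sum(a)
  if (tot <= 0) stop("greenness undefined for an all-black patch")
  sum(a[, , 2]) / tot
}
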