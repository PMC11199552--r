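# Small cohorts built in code for unit tests.

make_ped <- function(roles_by_family, locations = NULL) {
  rows <- list()
  for (f in seq_along(roles_by_family)) {
    roles <- roles_by_family[[f]]
    loc <- if (is.null(locations)) "locA" else locations[f]
    rows[[f]] <- data.frame(
      individual_id = sprintf("f%d_i%d", f, seq_along(roles)),
      family_id = sprintf("f%02d", f),
      role = roles,
      sex = ifelse(roles == "mother", "F", "M"),
      birth_year = 1970 + seq_along(roles),
      months_enrolled = 84,
      location_id = loc,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

quad_roles <- c("father", "mother", "child", "child")

# 3 families (quad, trio, quint) on 2 locations; N = 11
toy_cohort <- function() {
  ped <- make_ped(list(quad_roles,
                       c("father", "mother", "child"),
                       c("father", "mother", "child", "child", "child")),
                  locations = c("locA", "locB", "locA"))
  smile_cohort(ped)
}

toy_graph2 <- function() location_graph(cbind("locA", "locB"), c("locA", "locB"))
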