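# shared builders for the test suite (all fixtures are constructed in code)

std_lesion <- function(ds = 0.7, len = 5, cs = "concentric",
                       profile = "rounded", taper = "focal",
                       center = NA_real_) {
  lesion_spec(ds, len, cross_section = cs, profile = profile, taper = taper,
              center_mm = center)
}

std_vessel <- function(lesions = list(), L = 50, D = 3.5) {
  segment_spec(D, L, lesions)
}

std_profile <- function(lesions = list(), L = 50, D = 3.5, step = 0.1) {
  build_area_profile(std_vessel(lesions, L, D), step)
}

# a representative slice of the study's straight-vessel archetypes, used by
# the oracle-equivalence and property tests (ds, len, n, taper, profile, cs)
sweep_cases <- function() {
  rbind(
    data.frame(ds = 0.5, len = 5, n = 1, taper = "focal", profile = "rounded", cs = "concentric", L = 50),
    data.frame(ds = 0.7, len = 5, n = 1, taper = "focal", profile = "rounded", cs = "concentric", L = 50),
    data.frame(ds = 0.8, len = 5, n = 1, taper = "focal", profile = "rounded", cs = "eccentric", L = 50),
    data.frame(ds = 0.7, len = 5, n = 1, taper = "focal", profile = "rectangular", cs = "concentric", L = 50),
    data.frame(ds = 0.8, len = 5, n = 1, taper = "focal", profile = "rectangular", cs = "concentric", L = 50),
    data.frame(ds = 0.7, len = 10, n = 1, taper = "uniform", profile = "rounded", cs = "concentric", L = 100),
    data.frame(ds = 0.7, len = 30, n = 1, taper = "uniform", profile = "rounded", cs = "concentric", L = 100),
    data.frame(ds = 0.8, len = 20, n = 1, taper = "uniform", profile = "rounded", cs = "eccentric", L = 100),
    data.frame(ds = 0.7, len = 5, n = 2, taper = "focal", profile = "rounded", cs = "concentric", L = 100),
    data.frame(ds = 0.7, len = 5, n = 3, taper = "uniform", profile = "rounded", cs = "concentric", L = 100))
}

case_segment <- function(cc) {
  les <- rep(list(std_lesion(cc$ds, cc$len, cc$cs, cc$profile, cc$taper)),
             cc$n)
  segment_spec(3.5, cc$L, les)
}

case_oracle_lesions <- function(cc) {
  centers <- oracle_place(cc$n, cc$len, cc$L)
  lapply(centers, function(cen) {
    list(ds = cc$ds, len = cc$len, center = cen, cs = cc$cs,
         profile = cc$profile, taper = cc$taper)
  })
}
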