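# shared fixtures, built in code

std_track <- function(objects = default_object_arcs()) {
  circular_track(106.7, 15, object_arcs_cm = objects)
}

open_boxes <- function() {
  list(A = rect_env(61, 61), B = rect_env(122, 122),
       C = rect_env(61, 122), D = rect_env(122, 61))
}

# Fig-4-style two-input setup: narrow observation field, wide prior field
fig4_inputs <- function() {
  list(prior = gaussian_rate_field(60, 10, 25),
       obs = gaussian_rate_field(40, 5, 50))
}

fig4_traj <- function(duration_s = 60) {
  gen_trajectory(rect_env(100, 10), speed_cm_s = 20, duration_s = duration_s)
}
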