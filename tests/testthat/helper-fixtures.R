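# Shared fixtures, all generated in code.

# small, fast-replicating parameter set used by many simulator tests
quick_params <- function(...) {
  args <- utils::modifyList(
    list(N0 = 50, J = 5, Pout = 0.002, Pin = 0.2, Plocal = 0.2,
         theta = 0.3, d = 20),
    list(...))
  do.call(model_parameters, args)
}

# the published MM5 example parameter set, with N0 and J scaled to the
# lattice size (reference genome: 1e6 kb)
fig_params <- function(L = 1e6) {
  scale <- L / 1e6
  model_parameters(N0 = 1231 * scale, J = 287 * scale, theta = 0.46,
                   Pin = 0.34, Plocal = 0.34, Pout = 0.01, d = 138,
                   variant = "MM5", origin_layout = "discrete")
}

# build a combing dataset from a list of 0/1 molecule tracks
dataset_from_tracks <- function(tracks) {
  molecules <- tibble::tibble(molecule_id = seq_along(tracks),
                              length_kb = lengths(tracks))
  eyes <- purrr::map_dfr(seq_along(tracks), function(i) {
    m <- eyes_from_bits(tracks[[i]])
    if (nrow(m) == 0) return(NULL)
    tibble::tibble(molecule_id = i, start = m[, 1], end = m[, 2])
  })
  if (nrow(eyes) == 0) {
    eyes <- tibble::tibble(molecule_id = integer(0), start = numeric(0),
                           end = numeric(0))
  }
  combing_dataset(molecules, eyes, "experimental")
}

# observable_curves object with hand-set i_rate values and zeroed rest
make_toy_curves <- function(values) {
  ds <- dataset_from_tracks(list(c(0, 1, 1, 0)))
  oc <- observable_curves(ds, f_bins = length(values))
  for (nm in names(oc)) oc[[nm]]$value <- 0
  oc$i_rate$value <- values
  oc
}

# run state forward n rounds with the R reference engine
run_steps <- function(state, p, map, mask, n) {
  for (i in seq_len(n)) state <- step(state, p, map, mask)
  state
}
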