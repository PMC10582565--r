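# graph and record fixtures built in code

mk_net <- function(g) as_brain_network(g)

path_net <- function(n) {
  mk_net(igraph::make_graph(as.vector(rbind(1:(n - 1), 2:n)), n = n,
                            directed = FALSE))
}
cycle_net <- function(n) mk_net(igraph::make_ring(n))
star_net <- function(leaves) mk_net(igraph::make_star(leaves + 1,
                                                      mode = "undirected"))
complete_net <- function(n) mk_net(igraph::make_full_graph(n))

random_gnp_net <- function(n, p, seed, connected = FALSE) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, p)
      if (!connected || igraph::is_connected(g)) break
    }
    mk_net(g)
  })
}

# plain data-frame view of a record set (provenance attributes stripped)
df_of <- function(x) {
  y <- as.data.frame(x)
  attributes(y) <- attributes(y)[c("names", "class", "row.names")]
  y
}

# one record row; direction XOR raw_r
rec_row <- function(study, a, b, direction = NA, raw_r = NA,
                    indicator = "FC", modality = "MRI",
                    n_patients = 20, n_controls = 20) {
  data.frame(study_id = study, modality = modality, indicator = indicator,
             region_a = a, region_b = b, direction = direction,
             raw_r = raw_r, n_patients = n_patients,
             n_controls = n_controls, stringsAsFactors = FALSE)
}

rec_df <- function(...) do.call(rbind, list(...))

# a signed core fixture on a tract triangle
triangle_tracts <- function() {
  tract_map(list(c("A", "B"), c("B", "C"), c("A", "C")))
}
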