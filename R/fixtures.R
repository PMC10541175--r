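#' Build a small deterministic fixture bundle
#'
#' In-memory bundle of miniature datasets (every task family), networks
#' (every connectivity and embedding kind) and one calibrated activity
#' matrix, used by the test suite and example code. Bit-stable across calls
#' with the same seed; everything is generated, nothing read from disk.
#'
#' @param seed base seed.
#' @return a named list with elements `datasets`, `networks`, `activity`.
#' @export
make_fixtures <- function(seed = 1) {
  datasets <- list(
    categorization = sample_random_categorization(P = 20, D = 10, epsilon = 0.1,
                                                  seed = derive_seed(seed, 11)),
    gp = sample_gp_task(P_train = 20, P_test = 20, D = 3, gamma = 1,
                        seed = derive_seed(seed, 12)),
    arm = sample_arm_task(P = 12, P_test = 12, dt = 2e-3,
                          seed = derive_seed(seed, 13)),
    vor = sample_vor_task(NULL, n_points = 40, P_train = 15,
                          seed = derive_seed(seed, 14))
  )
  networks <- list(
    dense = expansion_network(M = 200, D = 3, seed = derive_seed(seed, 21)),
    sparse_hom = expansion_network(M = 200, D = 3, N = 20, K = 4,
                                   weight_kind = "sparse_homogeneous",
                                   global_inhibition = TRUE,
                                   seed = derive_seed(seed, 22)),
    sparse_trunc = expansion_network(M = 200, D = 3, N = 20, K = 4,
                                     weight_kind = "sparse_truncnorm",
                                     global_inhibition = TRUE,
                                     seed = derive_seed(seed, 23)),
    clustered = expansion_network(M = 200, D = 3, N = 21, K = 4,
                                  weight_kind = "sparse_homogeneous",
                                  embedding = "clustered_blocks",
                                  seed = derive_seed(seed, 24))
  )
  net <- calibrate_threshold(networks$dense, datasets$gp$train_inputs, f = 0.3)
  activity <- expand(net, datasets$gp$test_inputs)
  list(datasets = datasets, networks = networks, activity = activity)
}
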