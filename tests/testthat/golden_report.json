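{
  "mutation_count": [20, 16, 8, 18, 15, 7, 17, 16, 10, 19, 17, 11, 14, 10, 8, 15, 11, 9],
  "tmb": [10.2040816326531, 9.26998841251448, 9.34579439252336, 9.18367346938776, 8.69061413673233, 8.17757009345794, 8.6734693877551, 9.26998841251448, 11.6822429906542, 9.69387755102041, 9.84936268829664, 12.8504672897196, 7.14285714285714, 5.79374275782155, 9.34579439252336, 7.6530612244898, 6.37311703360371, 10.5140186915888],
  "zscore": [1.22305323402153, 0.626376564471251, -0.566138517072297, 0.359721539418097, 0.284716620214205, -1.24550473755905, -0.0719443078836194, 0.626376564471251, 0.792593923901218, 0.791387386719812, 0.968036508728297, 1.47196014438797, -1.36694184978877, -1.42358310107102, -0.566138517072297, -0.93527600248705, -1.08192315681398, 0.11322770341446],
  "n_discordant": 1,
  "spearman_rho": 0.5,
  "wilcoxon_p": 0.75
}
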