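# Published hyperparameters of the compared detection methods.
gbm:
  learning_rate: 5
  max_depth: null
  min_samples_leaf: 1
  min_samples_split: 2
  n_estimators: 300
knn:
  n_neighbors: 3
  metric: manhattan
rf:
  max_depth: null
  max_leaf_nodes: null
  min_samples_leaf: 1
  min_samples_split: 2
  n_estimators: 100
drn:
  n_layers: 15
  hidden_width: 32
  epochs: 100
  batch_size: 32
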