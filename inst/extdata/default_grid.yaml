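# Packaged pipeline sweep: 6 classifier settings x 8 reducer settings = 48.
# PCA component counts stop at 100 (capped by training rows anyway for the
# sample sizes this sweep targets); F-test selection also includes k = 500.
standardize: true
classifiers:
  - type: linear_svm
    C: [0.1, 1.0]
  - type: rbf_svm
    C: [0.1, 1.0]
  - type: random_forest
    n_trees: [100, 500]
reducers:
  - type: none
  - type: pca
    k: [10, 50, 100]
  - type: f_select
    k: [10, 50, 100, 500]
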