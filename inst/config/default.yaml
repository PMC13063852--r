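# Default pipeline configuration (mirrors run_config() defaults).
margin_mm: 3.0        # peritumoral margin width
perturb_mm: 1.0       # contour erosion/dilation radius
target_mm: 1.0        # isotropic resampling voxel length
bin_width: 0.25       # histogram/GLCM bin width (z-score units)
alpha_univ: 0.05      # univariate Cox significance level
alpha_contour: 0.10   # contour-dependence significance level
rho_threshold: 0.8    # redundancy clustering |Spearman rho| threshold
min_unique: 3         # low-variability filter: minimum distinct values
min_cv: 0.001         # low-variability filter: minimum |SD/mean|
n_outer: 30           # outer splits
n_inner: 30           # inner splits per outer training set
train_frac: 0.8       # training fraction of every split
trim_k: 2.0           # ensemble trimming threshold in SD units
max_features: 4       # maximum Cox model size
feature_groups: [radiomic, clinical]
seed: 1
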