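"feature","icc"
"volume",0.9
"morph_voxel_count",0.754
"morph_surface_area",0.851
"morph_surface_volume_ratio",0.787
"morph_sphericity",0.844
"morph_compactness1",0.978
"morph_compactness2",0.647
"morph_spherical_disproportion",0.806
"morph_asphericity",0.892
"morph_max_diameter",0.752
"morph_major_axis",0.7
"morph_minor_axis",0.659
"morph_least_axis",0.86
"morph_elongation",0.83
"morph_flatness",0.853
"morph_vol_density_aabb",0.714
"morph_area_density_aabb",0.889
"morph_vol_density_aee",0.884
"morph_area_density_aee",0.331
"suv_max",0.67
"suv_mean",0.81
"suv_peak",0.848
"tlg",0.698
"loc_peak_global",0.641
"stat_min",0.945
"stat_median",0.844
"stat_p5",0.676
"stat_p10",0.76
"stat_p25",0.907
"stat_p75",0.753
"stat_p90",0.781
"stat_p95",0.871
"stat_iqr",0.945
"stat_range",0.908
"stat_variance",0.919
"stat_skewness",0.82
"stat_kurtosis",0.798
"stat_mad",0.92
"stat_rmad",0.636
"stat_medad",0.83
"stat_cov",0.795
"stat_qcod",0.527
"stat_energy",0.686
"stat_rms",0.89
"stat_com_shift",0.85
"ivh_v10",0.7
"ivh_v25",0.841
"ivh_v75",0.773
"ivh_v90",0.763
"ivh_i10",0.651
"ivh_i25",0.947
"ivh_i75",0.898
"ivh_i90",0.777
"ivh_v10_minus_v90",0.672
"ivh_i10_minus_i90",0.359
"ivh_auc",0.895
"ih_mean",0.939
"ih_variance",0.74
"ih_skewness",0.912
"ih_kurtosis",0.957
"ih_median",0.687
"ih_min",0.975
"ih_max",0.946
"ih_mode",0.489
"ih_p10",0.975
"ih_p25",0.966
"ih_p75",0.766
"ih_p90",0.742
"ih_iqr",0.905
"ih_range",0.634
"ih_mad",0.645
"ih_rmad",0.804
"ih_medad",0.731
"ih_cov",0.681
"ih_qcod",0.228
"ih_entropy",0.826
"ih_uniformity",0.937
"ih_max_gradient",0.538
"ih_max_gradient_level",0.429
"ih_min_gradient",0.421
"ih_min_gradient_level",0.237
"glcm_joint_max",0.79
"glcm_joint_average",0.917
"glcm_joint_variance",0.972
"glcm_joint_entropy",0.859
"glcm_diff_average",0.725
"glcm_diff_variance",0.82
"glcm_diff_entropy",0.66
"glcm_sum_average",0.923
"glcm_sum_variance",0.735
"glcm_sum_entropy",0.986
"glcm_energy",0.75
"glcm_contrast",0.989
"glcm_dissimilarity",0.691
"glcm_inv_diff",0.834
"glcm_inv_diff_norm",0.804
"glcm_inv_diff_mom",0.855
"glcm_inv_diff_mom_norm",0.8
"glcm_inv_variance",0.938
"glcm_correlation",0.904
"glcm_autocorrelation",0.697
"glcm_cluster_tendency",0.778
"glcm_cluster_shade",0.472
"glcm_cluster_prominence",0.501
"glcm_info_corr1",0.412
"glcm_info_corr2",0.669
"glrlm_sre",0.857
"glrlm_lre",0.988
"glrlm_lglre",0.715
"glrlm_hglre",0.773
"glrlm_srlgle",0.625
"glrlm_srhgle",0.776
"glrlm_lrlgle",0.413
"glrlm_lrhgle",0.911
"glrlm_glnu",0.543
"glrlm_glnu_norm",0.755
"glrlm_rlnu",0.341
"glrlm_rlnu_norm",0.829
"glrlm_run_percentage",0.836
"glrlm_gl_variance",0.867
"glrlm_rl_variance",0.692
"glrlm_run_entropy",0.942
"glszm_sze",0.638
"glszm_lze",0.368
"glszm_lglze",0.816
"glszm_hglze",0.867
"glszm_szlgle",0.837
"glszm_szhgle",0.741
"glszm_lzlgle",0.309
"glszm_lzhgle",0.705
"glszm_glnu",0.529
"glszm_glnu_norm",0.638
"glszm_zsnu",0.316
"glszm_zsnu_norm",0.89
"glszm_zone_percentage",0.807
"glszm_gl_variance",0.621
"glszm_zs_variance",0.939
"glszm_zs_entropy",0.698
"ngtdm_coarseness",0.725
"ngtdm_contrast",0.798
"ngtdm_busyness",0.333
"ngtdm_complexity",0.471
"ngtdm_strength",0.44
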