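task,model,sensitivity,ppv,f1_published
MI_1D,random_init,0.906077,0.762791,0.828283
MI_1D,pretrained,0.955801,0.762675,0.848386
MI_1D,pretrained_enhanced,0.909761,0.858384,0.883326
AF_1D,random_init,0.658537,0.723214,0.689362
AF_1D,pretrained,0.764228,0.912621,0.831858
AF_1D,pretrained_enhanced,0.853659,0.807692,0.83004
MI_2D,random_init,0,0,0
MI_2D,imagenet,0.824125,0.904954,0.862651
MI_2D,pretrained,0.513812,0.891374,0.651869
MI_2D,pretrained_enhanced,0.848066,0.88134,0.864383
MI_2D,mixed_modality,0.667587,0.884146,0.760756
AF_2D,random_init,0,0,0
AF_2D,imagenet,0.798611,0.845588,0.821429
AF_2D,pretrained,0.395833,0.808511,0.531469
AF_2D,pretrained_enhanced,0.801105,0.896907,0.846304
AF_2D,mixed_modality,0.657459,0.92129,0.767329
AF_2D,rule_based,0.53125,0.518644,0.524871
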