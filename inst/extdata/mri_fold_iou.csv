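condition,fold,iou
crossE,1,0.843
crossE,2,0.834
crossE,3,0.829
crossE,4,0.833
crossE,5,0.836
dice,1,0.848
dice,2,0.851
dice,3,0.864
dice,4,0.849
dice,5,0.852
iou11,1,0.836
iou11,2,0.875
iou11,3,0.855
iou11,4,0.876
iou11,5,0.857
iou0515,1,0.879
iou0515,2,0.901
iou0515,3,0.903
iou0515,4,0.895
iou0515,5,0.881
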