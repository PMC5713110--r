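table,set,actual,DI0,DI1,DI2,DI3,DI4,DI5,printed_accuracy_pct
full,calibration,DI0,23,6,0,0,1,0,76.67
full,calibration,DI1,3,43,0,0,0,0,93.48
full,calibration,DI2,0,0,46,0,0,0,100
full,calibration,DI3,1,0,0,44,0,1,95.65
full,calibration,DI4,0,0,0,0,46,0,100
full,calibration,DI5,0,0,0,0,0,29,100
full,prediction,DI0,9,5,0,0,1,0,60
full,prediction,DI1,1,22,0,0,0,0,95.65
full,prediction,DI2,0,0,23,0,0,0,100
full,prediction,DI3,0,0,0,22,0,1,95.65
full,prediction,DI4,0,0,0,0,23,0,100
full,prediction,DI5,0,0,0,0,0,15,100
spa,calibration,DI0,24,2,1,0,3,0,80
spa,calibration,DI1,5,40,0,0,1,0,86.96
spa,calibration,DI2,0,0,45,1,0,0,97.83
spa,calibration,DI3,0,0,1,44,0,1,95.65
spa,calibration,DI4,0,1,0,0,44,1,95.65
spa,calibration,DI5,0,0,0,0,1,28,96.55
spa,prediction,DI0,13,0,1,0,1,0,86.67
spa,prediction,DI1,4,18,0,0,1,0,78.26
spa,prediction,DI2,0,0,22,1,0,0,95.65
spa,prediction,DI3,0,0,0,22,0,1,95.65
spa,prediction,DI4,0,0,0,0,22,1,95.65
spa,prediction,DI5,0,0,0,0,1,14,93.33
texture,calibration,DI0,30,0,0,0,0,0,100
texture,calibration,DI1,9,25,3,5,3,1,54.35
texture,calibration,DI2,0,1,32,10,1,2,69.57
texture,calibration,DI3,0,5,10,26,2,3,56.52
texture,calibration,DI4,0,0,2,1,38,5,82.61
texture,calibration,DI5,0,0,0,4,2,23,79.31
texture,prediction,DI0,15,0,0,0,0,0,100
texture,prediction,DI1,3,12,2,3,3,0,52.17
texture,prediction,DI2,0,0,16,4,1,2,69.57
texture,prediction,DI3,0,2,6,14,0,1,60.87
texture,prediction,DI4,0,0,1,0,19,3,82.61
texture,prediction,DI5,0,0,0,2,0,13,86.67
fusion,calibration,DI0,29,1,0,0,0,0,100
fusion,calibration,DI1,4,42,0,0,0,0,82.61
fusion,calibration,DI2,0,1,45,0,0,0,95.65
fusion,calibration,DI3,0,0,1,44,1,0,100
fusion,calibration,DI4,0,1,0,2,43,0,95.65
fusion,calibration,DI5,0,0,0,0,1,28,100
fusion,prediction,DI0,15,0,0,0,0,0,100
fusion,prediction,DI1,4,19,0,0,0,0,82.61
fusion,prediction,DI2,0,1,22,0,0,0,95.65
fusion,prediction,DI3,0,0,0,23,0,0,100
fusion,prediction,DI4,0,0,0,1,22,0,95.65
fusion,prediction,DI5,0,0,0,0,0,15,100
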