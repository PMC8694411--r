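ranking,pts,standardization,method,interpreter,correct_id,correct_unclear,incorrect_id,incorrect_unclear,unknown,accuracy_all,accuracy_id
general,6,all,RBF,unanimous,69.1,0,2.4,0,28.5,96.6,96.6
general,6,all,RBF,best_match,69.1,4.1,2.4,0.8,23.6,95.7,96.6
general,6,all,RBF,dominant,69.1,3.3,2.4,1.6,23.6,94.7,96.6
general,4,raw,RBF,unanimous,70.1,0,4.2,0,25.8,94.4,94.4
general,4,all,RBF,unanimous,70.1,0,4.2,0,25.8,94.4,94.4
general,5,all,RBF,unanimous,72.7,0,6.3,0,21.0,92.0,92.0
general,4,all,RBF,dominant,70.1,7.2,4.2,3.6,15.0,90.9,94.4
general,5,raw,RBF,unanimous,72.7,0,7.7,0,19.6,90.4,90.4
general,4,all,RBF,best_match,70.1,6.6,4.2,4.2,15.0,90.1,94.4
general,6,raw,RBF,best_match,68.3,8.1,8.9,0.8,13.8,88.7,88.4
identified,6,raw,RBF,unanimous,68.3,0,0,8.9,22.8,88.4,100
identified,4,raw,KNN-3,dominant,25.2,52.7,0,22.2,0,77.8,100
identified,5,raw,KNN-3,dominant,29.3,49.7,0.6,20.4,0,79.0,98.0
identified,6,all,RBF,unanimous,69.1,0,2.4,0,28.5,96.6,96.6
identified,6,all,RBF,best_match,69.1,4.1,2.4,0.8,23.6,95.7,96.6
identified,6,all,RBF,dominant,69.1,3.3,2.4,1.6,23.6,94.7,96.6
identified,6,all,KNN-3,dominant,32.5,43.1,1.6,22.8,0,75.6,95.2
identified,4,raw,RBF,unanimous,70.1,0,4.2,0,25.8,94.4,94.4
identified,4,all,RBF,unanimous,70.1,0,4.2,0,25.8,94.4,94.4
identified,4,all,RBF,dominant,70.1,7.2,4.2,3.6,15.0,90.9,94.4
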